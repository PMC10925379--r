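#' Fit centering/scaling (and spatial sign) parameters on training rows
#'
#' Learns a per-feature center (training mean) and scale (sample standard
#' deviation, n-1 denominator). Zero-variance features are dropped from the
#' retained feature list with a warning and recorded. When
#' `spatial_sign = TRUE`, [apply_preprocess()] additionally projects each
#' standardized row onto the unit sphere (dividing by its Euclidean norm
#' across the retained features), a classical device to blunt the leverage
#' of outlying patients.
#'
#' @param table data.frame or matrix of training rows.
#' @param features character vector of feature columns to preprocess.
#' @param spatial_sign whether the sphere projection is part of the
#'   transform.
#' @return An object of class `uq_preproc` with fields `center`, `scale`,
#'   `features` (retained, in order), `dropped`, `spatial_sign`.
#' @export
fit_preprocess <- function(table, features = colnames(table),
                           spatial_sign = TRUE) {
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need at least 2 rows to fit preprocessing", call. = FALSE)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  drop <- sdev <= 0 | !is.finite(sdev)
  if (any(drop))
    warning("dropping zero-variance feature(s): ",
            paste(features[drop], collapse = ", "), call. = FALSE)
  keep <- features[!drop]
  # with a single retained feature the sphere projection degenerates to
  # sign(x), discarding all magnitude information; it needs >= 2 features
  structure(list(center = mu[keep], scale = sdev[keep], features = keep,
                 dropped = features[drop],
                 spatial_sign = isTRUE(spatial_sign) && length(keep) >= 2L),
            class = "uq_preproc")
}

#' Apply fitted preprocessing to a table
#'
#' Standardizes each retained feature with the training center/scale, then,
#' if enabled, divides each row by its Euclidean norm over the transformed
#' features (spatial sign). Rows of zero norm are left at zero with a
#' warning. The returned matrix is tagged so that applying the transform a
#' second time — which would not be idempotent under the sphere projection —
#' is refused.
#'
#' @param params a fitted `uq_preproc`.
#' @param table data.frame or matrix containing the params' features.
#' @return numeric matrix (rows × retained features) with attribute
#'   `preprocessed = TRUE`.
#' @export
apply_preprocess <- function(params, table) {
  stopifnot(inherits(params, "uq_preproc"))
  if (isTRUE(attr(table, "preprocessed")))
    stop("table has already been preprocessed; the transform is not idempotent",
         call. = FALSE)
  df <- as.data.frame(table)
  absent <- setdiff(params$features, names(df))
  if (length(absent))
    stop("feature(s) in params but absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  x <- as.matrix(df[, params$features, drop = FALSE])
  storage.mode(x) <- "double"
  x <- sweep(x, 2L, params$center, "-")
  x <- sweep(x, 2L, params$scale, "/")
  if (params$spatial_sign) {
    nrm <- sqrt(rowSums(x^2))
    zero <- nrm == 0
    if (any(zero))
      warning(sum(zero), " all-zero row(s) left unprojected by spatial sign",
              call. = FALSE)
    nrm[zero] <- 1
    x <- x / nrm
  }
  attr(x, "preprocessed") <- TRUE
  x
}

#' @export
print.uq_preproc <- function(x, ...) {
  cat("Preprocessing params:", length(x$features), "features",
      if (x$spatial_sign) "(center/scale + spatial sign)" else "(center/scale)",
      "\n")
  if (length(x$dropped))
    cat("  dropped zero-variance:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
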