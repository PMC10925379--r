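#' Specify a pseudo-bootstrapped ensemble
#'
#' The ensemble fits `n_models` base learners, each on a random subset of
#' `round(sample_fraction * n)` training rows drawn uniformly *without*
#' replacement ("pseudo-bootstrap"): the tunable fraction, rather than the
#' classical with-replacement draw, is what perturbs the members and makes
#' their disagreement a usable uncertainty signal.
#'
#' @param n_models number of base models B (>= 1).
#' @param sample_fraction fraction phi of training rows per member, in
#'   (0, 1\].
#' @param seed integer seed; fully determines the drawn subsets.
#' @return list of class `uq_ensemble_spec`.
#' @export
ensemble_spec <- function(n_models = 25L, sample_fraction = 0.95, seed = 1L) {
  stopifnot(n_models >= 1, sample_fraction > 0, sample_fraction <= 1)
  structure(list(n_models = as.integer(n_models),
                 sample_fraction = sample_fraction,
                 seed = as.integer(seed)),
            class = "uq_ensemble_spec")
}

#' Draw the pseudo-bootstrap row subsets for an ensemble
#'
#' @param n number of training rows (>= 2).
#' @param spec an [ensemble_spec()].
#' @return list of `n_models` integer index vectors, each of length
#'   `round(sample_fraction * n)`.
#' @export
draw_pseudo_bootstrap <- function(n, spec) {
  stopifnot(inherits(spec, "uq_ensemble_spec"), n >= 2L)
  m <- round(spec$sample_fraction * n)
  if (m < 2L) stop("subset size ", m, " is below 2; increase sample_fraction",
                   call. = FALSE)
  with_seed(spec$seed,
            lapply(seq_len(spec$n_models), function(b) sort(sample.int(n, m))))
}

#' Fit an uncertainty-quantifying ensemble
#'
#' Preprocessing (centering/scaling and, optionally, spatial sign) is fitted
#' once on the full training partition and shared by all members; members
#' are then fitted on their pseudo-bootstrap subsets of the transformed
#' rows. A subset that happens to contain a single outcome class is redrawn
#' with a shifted seed (up to 10 retries).
#'
#' @param data data.frame holding features and outcome.
#' @param features character vector of model features.
#' @param outcome name of the binary outcome column.
#' @param espec an [ensemble_spec()].
#' @param bspec a [base_learner_spec()].
#' @param spatial_sign include the sphere projection in preprocessing.
#' @return object of class `uq_ensemble` carrying the fitted members, the
#'   preprocessing parameters and both specs.
#' @export
fit_ensemble <- function(data, features, outcome, espec = ensemble_spec(),
                         bspec = base_learner_spec(), spatial_sign = TRUE) {
  stopifnot(inherits(espec, "uq_ensemble_spec"), inherits(bspec, "uq_base_spec"))
  df <- as.data.frame(data)
  y <- df[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training outcome has a single class", call. = FALSE)
  pre <- fit_preprocess(df, features, spatial_sign = spatial_sign)
  x <- apply_preprocess(pre, df)
  n <- nrow(x)
  subsets <- draw_pseudo_bootstrap(n, espec)
  members <- vector("list", espec$n_models)
  for (b in seq_along(subsets)) {
    idx <- subsets[[b]]
    tries <- 0L
    while (length(unique(y[idx])) < 2L) {
      tries <- tries + 1L
      if (tries > 10L)
        stop("member ", b, ": could not draw a two-class subset in 10 retries",
             call. = FALSE)
      idx <- with_seed(child_seed(espec$seed, b * 100L + tries),
                       sort(sample.int(n, length(idx))))
    }
    members[[b]] <- fit_base(x[idx, , drop = FALSE], y[idx], bspec)
  }
  if (espec$n_models == 1L)
    warning("single-member ensemble: predictive standard deviation will be 0",
            call. = FALSE)
  structure(list(members = members, preprocess = pre,
                 features = pre$features, outcome = outcome,
                 espec = espec, bspec = bspec, n_train = n),
            class = "uq_ensemble")
}

#' Predict with uncertainty from a fitted ensemble
#'
#' Each member predicts a response probability on the preprocessed rows;
#' the per-patient mean is the ensemble prediction and the per-patient
#' sample standard deviation (n-1 denominator; 0 for a single member)
#' quantifies its uncertainty.
#'
#' @param object a `uq_ensemble`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... unused.
#' @return object of class `uq_prediction`: list with `mean`, `std`
#'   (numeric vectors) and `members` (rows × B probability matrix).
#' @export
predict.uq_ensemble <- function(object, newdata, ...) {
  x <- apply_preprocess(object$preprocess, newdata)
  probs <- vapply(object$members, function(m) predict(m, x),
                  numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x))
  std <- if (ncol(probs) > 1L) apply(probs, 1L, stats::sd)
         else rep(0, nrow(probs))
  structure(list(mean = rowMeans(probs), std = std, members = probs),
            class = "uq_prediction")
}

#' @export
print.uq_ensemble <- function(x, ...) {
  cat(sprintf(
    "Pseudo-bootstrapped ensemble: B = %d, phi = %.2f, %d features, n = %d\n",
    x$espec$n_models, x$espec$sample_fraction, length(x$features), x$n_train))
  cat(sprintf("  base learner: elastic net (alpha = %.2f, lambda = %.4g)\n",
              x$bspec$alpha, x$bspec$lambda))
  invisible(x)
}

#' @export
print.uq_prediction <- function(x, ...) {
  cat(sprintf("Ensemble predictions for %d patients (B = %d members)\n",
              length(x$mean), ncol(x$members)))
  print(utils::head(data.frame(p_mean = x$mean, p_std = x$std)))
  if (length(x$mean) > 6L) cat("  ...\n")
  invisible(x)
}
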