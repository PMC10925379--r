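#' Load and validate a patient cohort
#'
#' Reads a CSV with a header row, checks it against a [feature_schema()],
#' enforces a binary outcome, applies the missing-data policy, and expands
#' multi-level categorical features to indicator columns (all levels
#' retained) so that downstream modelling sees a purely numeric table.
#'
#' @param path path to a CSV file with one row per patient.
#' @param schema an `uq_schema` describing the columns.
#' @param missing `"error"` (default) rejects any row with a missing
#'   feature or outcome, naming the first offending row and column;
#'   `"drop"` removes such rows and reports the count.
#' @return A list of class `uq_cohort` with elements `data` (validated,
#'   one-hot-expanded data.frame), `schema` (expanded schema) and
#'   `n_dropped`.
#' @export
load_cohort <- function(path, schema, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_cohort(df, schema, missing = missing)
}

#' Validate an in-memory cohort against a schema
#'
#' @param df data.frame with the schema's feature and outcome columns.
#' @inheritParams load_cohort
#' @return A `uq_cohort` (see [load_cohort()]).
#' @export
validate_cohort <- function(df, schema, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  stopifnot(inherits(schema, "uq_schema"))
  needed <- c(schema$features$name, schema$outcome)
  absent <- setdiff(needed, names(df))
  if (length(absent))
    stop("column(s) missing from cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  df <- df[, needed, drop = FALSE]

  all_na <- vapply(df[schema$features$name], function(x) all(is.na(x)), TRUE)
  if (any(all_na))
    stop("feature(s) entirely missing: ",
         paste(names(all_na)[all_na], collapse = ", "), call. = FALSE)

  n_dropped <- 0L
  bad_row <- apply(is.na(df), 1L, any)
  if (any(bad_row)) {
    if (missing == "error") {
      i <- which(bad_row)[1L]
      j <- names(df)[which(is.na(df[i, ]))[1L]]
      stop(sprintf("missing value at row %d, column '%s' (policy = error)", i, j),
           call. = FALSE)
    }
    n_dropped <- sum(bad_row)
    df <- df[!bad_row, , drop = FALSE]
    message(n_dropped, " row(s) with missing values dropped")
  }

  y <- df[[schema$outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome column '", schema$outcome, "' must contain only 0/1 values",
         call. = FALSE)
  df[[schema$outcome]] <- as.integer(y)

  for (i in seq_len(nrow(schema$features))) {
    nm <- schema$features$name[i]
    kind <- schema$features$kind[i]
    if (kind == "binary") {
      v <- df[[nm]]
      if (is.logical(v)) v <- as.integer(v)
      if (!all(v %in% c(0, 1)))
        stop("binary feature '", nm, "' contains non-0/1 values", call. = FALSE)
      df[[nm]] <- as.numeric(v)
    } else if (kind == "continuous") {
      if (!is.numeric(df[[nm]]))
        stop("continuous feature '", nm, "' is not numeric", call. = FALSE)
      df[[nm]] <- as.numeric(df[[nm]])
    }
  }

  expanded <- expand_categoricals(df, schema)
  structure(list(data = expanded$data, schema = expanded$schema,
                 n_dropped = n_dropped),
            class = "uq_cohort")
}

# One-hot expansion of categorical features, all levels retained (so that
# individual levels, e.g. each race or NYHA class, can carry their own
# coefficient and importance). Indicator columns inherit the parent's stage
# and become kind "binary".
expand_categoricals <- function(df, schema) {
  feats <- schema$features
  cat_rows <- which(feats$kind == "categorical")
  if (!length(cat_rows)) return(list(data = df, schema = schema))
  new_feats <- feats[feats$kind != "categorical", , drop = FALSE]
  for (i in cat_rows) {
    nm <- feats$name[i]
    v <- as.factor(df[[nm]])
    for (lev in levels(v)) {
      col <- paste0(nm, "_", lev)
      df[[col]] <- as.numeric(v == lev)
      new_feats <- rbind(new_feats,
                         data.frame(name = col, kind = "binary",
                                    stage = feats$stage[i]))
    }
    df[[nm]] <- NULL
  }
  schema2 <- feature_schema(new_feats, schema$outcome)
  list(data = df[, c(schema2$features$name, schema2$outcome), drop = FALSE],
       schema = schema2)
}

#' Split a cohort into stage-1 and stage-2 views
#'
#' The stage-1 view carries only stage-1 features; the stage-2 view carries
#' stage-1 plus stage-2 features (a strict superset), both with the outcome
#' column and identical row order.
#'
#' @param cohort a `uq_cohort` or a data.frame (then `schema` is required).
#' @param schema the `uq_schema` (ignored when `cohort` is a `uq_cohort`).
#' @param cascade if `TRUE` (default) require both stages to be populated.
#' @return list with elements `stage1` and `stage2` (data.frames).
#' @export
split_stages <- function(cohort, schema = NULL, cascade = TRUE) {
  if (inherits(cohort, "uq_cohort")) {
    schema <- cohort$schema
    df <- cohort$data
  } else df <- cohort
  stopifnot(inherits(schema, "uq_schema"))
  if (cascade) assert_cascade_schema(schema)
  s1 <- stage_features(schema, 1L)
  s2 <- stage_features(schema, c(1L, 2L))
  list(stage1 = df[, c(s1, schema$outcome), drop = FALSE],
       stage2 = df[, c(s2, schema$outcome), drop = FALSE])
}

#' @export
print.uq_cohort <- function(x, ...) {
  cat("Validated cohort:", nrow(x$data), "patients,",
      nrow(x$schema$features), "features",
      sprintf("(%d stage-1, %d stage-2);", sum(x$schema$features$stage == 1L),
              sum(x$schema$features$stage == 2L)),
      "outcome prevalence",
      sprintf("%.1f%%\n", 100 * mean(x$data[[x$schema$outcome]])))
  invisible(x)
}
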