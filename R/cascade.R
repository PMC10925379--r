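#' Configuration for fitting the multi-stage cascade
#'
#' Collects every tunable of the fitting pipeline in one place. Defaults
#' follow the study protocol: validation slices of about a tenth of the
#' training rows each, recursive feature elimination per stage, a 25-member
#' ensemble trained on 95% subsamples, threshold grids tau_sigma in
#' 0.01–0.20 (step 0.01) and tau_m in 0.02–0.10 (step 0.01), and scaling
#' parameters {0.5, 1, 2, ..., 9}.
#'
#' @param val1_size,val2_size rows in each validation slice (`NULL` =
#'   `round(n/10)`).
#' @param rfe run recursive feature elimination per stage.
#' @param rfe_folds folds for the RFE selection CV.
#' @param tune tune ensemble hyperparameters by inner CV (otherwise the
#'   fixed `espec`/`bspec` are used).
#' @param tune_grid grid for [tune_ensemble()] when `tune = TRUE`.
#' @param inner_folds inner-CV folds for tuning.
#' @param espec default [ensemble_spec()] (seed is reassigned per fit).
#' @param bspec default [base_learner_spec()].
#' @param std_grid,mid_grid,s_grid gate-tuning grids.
#' @param weight_form gate-objective weight shape, see
#'   [scaling_weight_fn()].
#' @param spatial_sign include the sphere projection in preprocessing.
#' @return list of class `uq_cascade_config`.
#' @export
cascade_config <- function(val1_size = NULL, val2_size = NULL,
                           rfe = TRUE, rfe_folds = 5L,
                           tune = FALSE, tune_grid = NULL, inner_folds = 5L,
                           espec = ensemble_spec(25L, 0.95),
                           bspec = base_learner_spec(0.5, 0.01),
                           std_grid = seq(0.01, 0.20, by = 0.01),
                           mid_grid = seq(0.02, 0.10, by = 0.01),
                           s_grid = c(0.5, 1:9),
                           weight_form = c("saturating", "power"),
                           spatial_sign = TRUE) {
  structure(list(val1_size = val1_size, val2_size = val2_size,
                 rfe = rfe, rfe_folds = rfe_folds,
                 tune = tune, tune_grid = tune_grid,
                 inner_folds = inner_folds,
                 espec = espec, bspec = bspec,
                 std_grid = std_grid, mid_grid = mid_grid, s_grid = s_grid,
                 weight_form = match.arg(weight_form),
                 spatial_sign = spatial_sign),
            class = "uq_cascade_config")
}

#' Fit the uncertainty-gated multi-stage cascade
#'
#' The main fitting function. From the supplied training cohort it slices
#' off two stratified validation sets, optionally runs recursive feature
#' elimination and inner-CV hyperparameter tuning per stage on the
#' remaining rows, fits Ensemble 1 (stage-1 features) and Ensemble 2
#' (stage-1 + stage-2 features) there, tunes the gate thresholds on
#' validation 1 under every scaling parameter in the grid, and selects the
#' final policy by plain AUC on validation 2.
#'
#' @param data training cohort: a `uq_cohort` or a validated data.frame.
#' @param schema the `uq_schema` (taken from `data` when it is a
#'   `uq_cohort`).
#' @param config a [cascade_config()].
#' @param seed integer seed governing every random draw of the fit.
#' @return object of class `cascade_fit` with components `ensemble1`,
#'   `ensemble2`, `policy`, `candidates` (per-s policies), `features`
#'   (per stage, post-selection), `indices` (train/val1/val2 row indices
#'   into `data`), `schema`, `config`, `seed`.
#' @seealso [predict.cascade_fit()], [run_nested_cv()]
#' @export
cascade_fit <- function(data, schema = NULL, config = cascade_config(),
                        seed = 1L) {
  if (inherits(data, "uq_cohort")) { schema <- data$schema; df <- data$data }
  else df <- as.data.frame(data)
  stopifnot(inherits(schema, "uq_schema"), inherits(config, "uq_cascade_config"))
  assert_cascade_schema(schema)
  y <- df[[schema$outcome]]
  n <- nrow(df)
  v1 <- config$val1_size %||% max(2L, round(n / 10))
  v2 <- config$val2_size %||% max(2L, round(n / 10))
  if (n - v1 - v2 < 4L) stop("too few rows for the validation slices", call. = FALSE)

  # stratified validation slices; redraw with a shifted seed if a slice or
  # the remaining train collapses to one class
  slice_seed <- child_seed(seed, 1L)
  for (try in 0:10) {
    idx_v1 <- stratified_sample(y, v1, slice_seed + try)
    rest <- setdiff(seq_len(n), idx_v1)
    idx_v2 <- rest[stratified_sample(y[rest], v2, slice_seed + try + 50L)]
    idx_tr <- setdiff(rest, idx_v2)
    ok <- length(unique(y[idx_tr])) == 2L && length(unique(y[idx_v1])) == 2L &&
      length(unique(y[idx_v2])) == 2L
    if (ok) break
  }
  if (!ok) stop("could not slice two-class validation sets", call. = FALSE)

  train <- df[idx_tr, , drop = FALSE]
  s1_all <- stage_features(schema, 1L)
  s2_all <- stage_features(schema, c(1L, 2L))

  fit_stage <- function(feats, stream) {
    bspec <- config$bspec
    espec <- config$espec
    if (config$rfe && length(feats) > 1L)
      feats <- as.character(select_features_rfe(
        train, feats, schema$outcome, bspec, config$rfe_folds,
        seed = child_seed(seed, stream), spatial_sign = config$spatial_sign))
    if (config$tune) {
      args <- list(train, feats, schema$outcome,
                   inner_folds = config$inner_folds,
                   seed = child_seed(seed, stream + 1L),
                   spatial_sign = config$spatial_sign)
      if (!is.null(config$tune_grid)) args$grid <- config$tune_grid
      tuned <- do.call(tune_ensemble, args)
      espec <- tuned$espec; bspec <- tuned$bspec
    }
    espec$seed <- child_seed(seed, stream + 2L)
    ens <- fit_ensemble(train, feats, schema$outcome, espec, bspec,
                        spatial_sign = config$spatial_sign)
    list(ens = ens, features = feats)
  }
  st1 <- fit_stage(s1_all, 10L)
  st2 <- fit_stage(s2_all, 20L)

  candidates <- lapply(config$s_grid, function(s)
    tune_thresholds(st1$ens, st2$ens, df[idx_v1, , drop = FALSE],
                    schema$outcome, s,
                    std_grid = config$std_grid, mid_grid = config$mid_grid,
                    form = config$weight_form %||% "saturating"))
  policy <- select_scaling(st1$ens, st2$ens, df[idx_v2, , drop = FALSE],
                           schema$outcome, candidates)

  structure(list(ensemble1 = st1$ens, ensemble2 = st2$ens,
                 policy = policy, candidates = candidates,
                 features = list(stage1 = st1$features, stage2 = st2$features),
                 indices = list(train = idx_tr, val1 = idx_v1, val2 = idx_v2),
                 schema = schema, config = config, seed = as.integer(seed),
                 n = n),
            class = "cascade_fit")
}

#' Predict from a fitted cascade
#'
#' @param object a `cascade_fit`.
#' @param newdata data.frame of new patients (stage-2 features needed only
#'   for rows the gate escalates).
#' @param type `"cascade"` (default) for the gated prediction,
#'   `"ensemble1"` / `"ensemble2"` for the raw stage predictions.
#' @param ... unused.
#' @return for `"cascade"`, a `uq_cascade_prediction` data.frame
#'   (`final_prob`, `stage_used`, `reason`; attribute `fraction_stage1`);
#'   otherwise a `uq_prediction`.
#' @export
predict.cascade_fit <- function(object, newdata,
                                type = c("cascade", "ensemble1", "ensemble2"),
                                ...) {
  type <- match.arg(type)
  switch(type,
         cascade = predict_cascade(object$ensemble1, object$ensemble2,
                                   object$policy, newdata),
         ensemble1 = predict(object$ensemble1, newdata),
         ensemble2 = predict(object$ensemble2, newdata))
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat("Uncertainty-gated two-stage cascade\n")
  cat(sprintf("  trained on %d rows (validation slices: %d + %d)\n",
              length(x$indices$train), length(x$indices$val1),
              length(x$indices$val2)))
  cat(sprintf("  Ensemble 1: %d features | Ensemble 2: %d features\n",
              length(x$features$stage1), length(x$features$stage2)))
  print(x$policy)
  invisible(x)
}

#' @export
summary.cascade_fit <- function(object, ...) {
  pol <- object$policy
  cands <- data.frame(
    s = vapply(object$candidates, function(p) p$scaling_weight, 0),
    std_threshold = vapply(object$candidates, function(p) p$std_threshold, 0),
    midway_threshold = vapply(object$candidates, function(p) p$midway_threshold, 0),
    val1_objective = vapply(object$candidates, function(p) attr(p, "objective"), 0),
    val1_f = vapply(object$candidates, function(p) attr(p, "f"), 0))
  out <- list(policy = pol, candidates = cands,
              val2_auc = attr(pol, "val2_auc"), val2_f = attr(pol, "val2_f"),
              ensemble1 = object$ensemble1$espec,
              ensemble2 = object$ensemble2$espec,
              features = object$features)
  class(out) <- "summary.cascade_fit"
  out
}

#' @export
print.summary.cascade_fit <- function(x, ...) {
  print(x$policy)
  cat(sprintf("  validation-2 AUC %.3f, stage-1 fraction %.2f\n",
              x$val2_auc, x$val2_f))
  cat("Per-scaling-parameter candidates:\n")
  print(x$candidates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Ensemble-averaged coefficients of a fitted cascade
#'
#' @param object a `cascade_fit`.
#' @param ... unused.
#' @return list with `ensemble1` and `ensemble2`: named vectors of member-
#'   averaged slopes (on the preprocessed scale), intercept first.
#' @export
coef.cascade_fit <- function(object, ...) {
  avg <- function(ens) {
    betas <- vapply(ens$members, function(m) c(`(Intercept)` = m$intercept, m$beta),
                    numeric(length(ens$members[[1]]$beta) + 1L))
    if (is.null(dim(betas))) betas <- matrix(betas, ncol = length(ens$members))
    rowMeans(betas)
  }
  list(ensemble1 = avg(object$ensemble1), ensemble2 = avg(object$ensemble2))
}
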