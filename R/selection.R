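#' Recursive feature elimination for the elastic-net base learner
#'
#' Starting from the full feature set, a base learner is fitted on the
#' standardized (and optionally sphere-projected) training rows and
#' features are ranked by absolute coefficient; the set is halved down a
#' fixed schedule (p, p/2, ..., 1). The retained subset is the smallest
#' one whose cross-validated AUC comes within `tol` of the best schedule
#' entry (the usual parsimony rule; `tol = 0` reduces to the strict
#' maximum with ties going to the smaller subset).
#'
#' @param data data.frame with features and outcome.
#' @param features candidate feature names (>= 1).
#' @param outcome binary outcome column name.
#' @param bspec a [base_learner_spec()].
#' @param cv_folds folds for the selection CV.
#' @param seed integer seed for fold assignment.
#' @param spatial_sign include the sphere projection in preprocessing.
#' @param tol parsimony tolerance on the CV AUC.
#' @return character vector: the selected features, in ranking order, with
#'   attribute `cv_auc` (named by subset size).
#' @export
select_features_rfe <- function(data, features, outcome,
                                bspec = base_learner_spec(), cv_folds = 5L,
                                seed = 1L, spatial_sign = TRUE, tol = 0.002) {
  df <- as.data.frame(data)
  y <- df[[outcome]]
  if (length(features) < 1L) stop("no candidate features", call. = FALSE)
  if (length(features) == 1L) return(features)

  sizes <- length(features)
  while (sizes[length(sizes)] > 1L)
    sizes <- c(sizes, floor(sizes[length(sizes)] / 2))

  # Iterative elimination: refit and re-rank at each schedule step.
  subsets <- vector("list", length(sizes))
  current <- features
  for (k in seq_along(sizes)) {
    current <- rank_features(df, current, y, bspec, spatial_sign)[seq_len(sizes[k])]
    subsets[[k]] <- current
  }

  fold <- stratified_folds(y, cv_folds, seed)
  cv_auc <- vapply(subsets, function(fs) {
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) return(NA_real_)
      pre <- suppressWarnings(fit_preprocess(df[tr, , drop = FALSE], fs,
                                             spatial_sign = spatial_sign))
      if (!length(pre$features)) return(NA_real_)
      m <- fit_base(apply_preprocess(pre, df[tr, , drop = FALSE]), y[tr], bspec)
      roc_auc(y[te], predict(m, apply_preprocess(pre, df[te, , drop = FALSE])))
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)

  # smallest subset within tol of the best; exact ties -> smaller subset
  ok <- which(cv_auc >= max(cv_auc, na.rm = TRUE) - tol)
  best <- max(ok)
  out <- subsets[[best]]
  names(cv_auc) <- sizes
  attr(out, "cv_auc") <- cv_auc
  out
}

# Rank features by |coefficient| of a base-learner fit on preprocessed data.
rank_features <- function(df, features, y, bspec, spatial_sign) {
  pre <- suppressWarnings(fit_preprocess(df, features, spatial_sign = spatial_sign))
  if (!length(pre$features)) return(features)
  fit <- fit_base(apply_preprocess(pre, df), y, bspec)
  ranked <- names(sort(abs(fit$beta), decreasing = TRUE))
  c(ranked, setdiff(features, ranked))
}

#' Tune ensemble and base-learner hyperparameters by inner cross-validation
#'
#' Exhaustive search over the supplied grids; for every grid point an
#' ensemble is fitted on each inner-CV training part and scored by AUC of
#' its mean probability on the held-out part. The point with the highest
#' mean inner-CV AUC wins; ties go to fewer base models, then to a larger
#' sample fraction.
#'
#' @param data data.frame with features and outcome.
#' @param features model features.
#' @param outcome binary outcome column name.
#' @param grid named list of candidate values: `n_models`,
#'   `sample_fraction`, `alpha`, `lambda` (each a numeric vector).
#' @param inner_folds number of inner-CV folds.
#' @param seed integer seed.
#' @param spatial_sign passed to [fit_ensemble()].
#' @return list with `espec`, `bspec`, and `results` (the scored grid).
#' @export
tune_ensemble <- function(data, features, outcome,
                          grid = list(n_models = c(25, 34, 37, 40, 49),
                                      sample_fraction = c(0.70, 0.84, 0.85, 0.86, 0.95),
                                      alpha = 0.5, lambda = 0.01),
                          inner_folds = 5L, seed = 1L, spatial_sign = TRUE) {
  if (!length(grid) || any(!lengths(grid)))
    stop("hyperparameter grid is empty", call. = FALSE)
  grid <- utils::modifyList(
    list(n_models = 25, sample_fraction = 0.95, alpha = 0.5, lambda = 0.01),
    grid)
  pts <- expand.grid(n_models = grid$n_models,
                     sample_fraction = grid$sample_fraction,
                     alpha = grid$alpha, lambda = grid$lambda)
  df <- as.data.frame(data)
  y <- df[[outcome]]
  fold <- stratified_folds(y, inner_folds, seed)
  pts$auc <- vapply(seq_len(nrow(pts)), function(i) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2L) return(NA_real_)
      ens <- fit_ensemble(df[tr, , drop = FALSE], features, outcome,
                          espec = ensemble_spec(pts$n_models[i],
                                                pts$sample_fraction[i],
                                                seed = child_seed(seed, f)),
                          bspec = base_learner_spec(pts$alpha[i], pts$lambda[i]),
                          spatial_sign = spatial_sign)
      roc_auc(y[!tr], predict(ens, df[!tr, , drop = FALSE])$mean)
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  ord <- order(-pts$auc, pts$n_models, -pts$sample_fraction)
  best <- pts[ord[1L], ]
  list(espec = ensemble_spec(best$n_models, best$sample_fraction, seed = seed),
       bspec = base_learner_spec(best$alpha, best$lambda),
       results = pts)
}
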