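#' Permutation feature importance for an ensemble
#'
#' For each member and each feature, the feature's column is shuffled
#' `n_permutations` times and the member's AUC drop from its baseline is
#' averaged; member importances are then averaged within the ensemble. A
#' feature carrying no information has importance near zero (up to
#' Monte-Carlo error); aggregation of absolute values across CV folds is
#' left to the caller (see [run_nested_cv()] results).
#'
#' @param model a fitted `uq_ensemble`.
#' @param data data.frame with the model's features and outcome.
#' @param outcome binary outcome column name.
#' @param n_permutations shuffles per feature (>= 1).
#' @param seed integer seed.
#' @return named numeric vector of mean AUC drops, one per model feature,
#'   sorted decreasing.
#' @export
permutation_importance <- function(model, data, outcome,
                                   n_permutations = 10L, seed = 1L) {
  stopifnot(inherits(model, "uq_ensemble"), n_permutations >= 1L)
  df <- as.data.frame(data)
  y <- df[[outcome]]
  x <- apply_preprocess(model$preprocess, df)
  feats <- colnames(x)
  base_auc <- vapply(model$members, function(m) roc_auc(y, predict(m, x)), 0)
  perms <- with_seed(seed, lapply(seq_len(n_permutations),
                                  function(i) sample.int(nrow(x))))
  imp <- vapply(feats, function(f) {
    drops <- vapply(perms, function(p) {
      dfp <- df
      dfp[[f]] <- df[[f]][p]
      xp <- apply_preprocess(model$preprocess, dfp)
      permuted <- vapply(model$members, function(m) roc_auc(y, predict(m, xp)), 0)
      mean(base_auc - permuted)
    }, 0)
    mean(drops)
  }, 0)
  sort(imp, decreasing = TRUE)
}
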