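# Shared fixtures and independent oracles used across the suite.

# Brute-force all-pairs AUC: the oracle roc_auc() must match exactly.
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Stratified-bootstrap two-sided p-value for the AUC difference of two
# paired score vectors; independent check of the DeLong test.
delta_auc_bootstrap_p <- function(labels, a, b, reps = 10000L, seed = 1L) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  deltas <- withr::with_seed(seed, vapply(seq_len(reps), function(r) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    roc_auc(labels[idx], a[idx]) - roc_auc(labels[idx], b[idx])
  }, 0))
  2 * min(mean(deltas <= 0), mean(deltas >= 0))
}

# Generic-optimizer fit of the elastic-net logistic objective that
# fit_base()/glmnet minimizes: mean negative log-likelihood plus
# lambda * (alpha*L1 + (1-alpha)/2*L2) on the slopes.
enet_logistic_optim <- function(x, y, alpha, lambda) {
  n <- nrow(x)
  obj <- function(par) {
    b0 <- par[1]; b <- par[-1]
    eta <- drop(x %*% b) + b0
    -mean(y * eta - log1p(exp(eta))) +
      lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
  }
  fit <- stats::optim(rep(0, ncol(x) + 1L), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(intercept = fit$par[1], beta = fit$par[-1])
}

# A tiny two-stage schema + data.frame for plumbing tests.
toy_schema <- function() {
  feature_schema(
    data.frame(name = c("age", "qrsd", "lvef", "psd"),
               kind = "continuous",
               stage = c(1, 1, 2, 2)),
    outcome = "response")
}

toy_df <- function() {
  data.frame(age = c(60, 55, 70, 65), qrsd = c(150, 120, 160, 140),
             lvef = c(30, 40, 25, 35), psd = c(50, 42, 61, 48),
             response = c(0, 1, 0, 1))
}

# Small fitted ensemble pair on a synthetic cohort, reused by gate tests.
fit_toy_ensembles <- function(n = 160, seed = 42) {
  sc <- synth_cohort(synth_spec(n = n, rho = 0.4, seed = seed))
  df <- sc$cohort$data
  s1 <- grep("^s1", names(df), value = TRUE)
  s2 <- grep("^s", names(df), value = TRUE)
  list(
    ens1 = fit_ensemble(df, s1, "response", ensemble_spec(8L, 0.8, seed = 1)),
    ens2 = fit_ensemble(df, s2, "response", ensemble_spec(8L, 0.8, seed = 2)),
    data = df, truth = sc$truth, schema = sc$cohort$schema)
}
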