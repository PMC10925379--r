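#' Specify a synthetic two-stage cohort
#'
#' The generator emulates the modelled cohort's structure: a binary
#' response with target prevalence ~55.5%, 14 stage-1 features (clinical +
#' ECG analogue) and 30 stage-2 features (SPECT analogue), a mix of
#' continuous and binary columns, and an "ambiguous subgroup" — the
#' fraction `rho` of patients whose stage-1 linear predictor lies nearest
#' its cohort median, for whom the residual stage-1 signal is attenuated
#' and the outcome is driven by the stage-2 features instead. That
#' construction makes stage-1 predictions for subgroup members both
#' equivocal (near the decision midpoint) and unstable under subsampling —
#' the uncertainty signal the gate exploits — while stage-2 features carry
#' real incremental signal there.
#'
#' @param n number of patients (>= 20).
#' @param prevalence target outcome prevalence in (0, 1).
#' @param rho ambiguous-subgroup fraction in \[0, 1\].
#' @param n_cont1,n_bin1 continuous/binary stage-1 feature counts.
#' @param n_cont2,n_bin2 continuous/binary stage-2 feature counts.
#' @param beta1,beta2 coefficient vectors (recycled/zero-padded to the
#'   per-stage feature count; defaults give ~6 informative features per
#'   stage with decaying alternating-sign effects).
#' @param effect_size multiplier on both coefficient vectors.
#' @param attenuation factor shrinking the subgroup's residual stage-1
#'   signal toward the median (0 = fully uninformative there).
#' @param rho_x AR(1) correlation between continuous features in a stage.
#' @param seed integer seed.
#' @return list of class `uq_synth_spec`.
#' @export
synth_spec <- function(n = 218L, prevalence = 0.555, rho = 0.4,
                       n_cont1 = 8L, n_bin1 = 6L, n_cont2 = 24L, n_bin2 = 6L,
                       beta1 = NULL, beta2 = NULL, effect_size = 1,
                       attenuation = 0.1, rho_x = 0.2, seed = 1L) {
  stopifnot(n >= 20L, prevalence > 0, prevalence < 1, rho >= 0, rho <= 1,
            attenuation >= 0, attenuation <= 1)
  p1 <- n_cont1 + n_bin1
  p2 <- n_cont2 + n_bin2
  default_beta <- function(p, scale = 1) {
    k <- min(6L, p)
    b <- numeric(p)
    b[seq_len(k)] <- scale * c(1.2, -1.0, 0.8, -0.7, 0.6, 0.5)[seq_len(k)]
    b
  }
  # stage-1 effects follow the base pattern (routine clinical variables are
  # informative outside the subgroup); stage-2 effects are strong, as the
  # subgroup's outcome is driven by the expensive modality and its
  # cohort-level signal is diluted by the subgroup fraction in a global fit
  beta1 <- rep_len(beta1 %||% default_beta(p1, 0.55), p1) * effect_size
  beta2 <- rep_len(beta2 %||% default_beta(p2, 2), p2) * effect_size
  structure(list(n = as.integer(n), prevalence = prevalence, rho = rho,
                 n_cont1 = n_cont1, n_bin1 = n_bin1,
                 n_cont2 = n_cont2, n_bin2 = n_bin2,
                 beta1 = beta1, beta2 = beta2,
                 attenuation = attenuation, rho_x = rho_x,
                 seed = as.integer(seed)),
            class = "uq_synth_spec")
}

# AR(1)-correlated standard normal block.
ar1_block <- function(n, p, rho_x) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (p > 1L && rho_x > 0) {
    for (j in 2:p) z[, j] <- rho_x * z[, j - 1L] + sqrt(1 - rho_x^2) * z[, j]
  }
  z
}

#' Generate a synthetic cohort with known ground truth
#'
#' Outcomes are Bernoulli draws from a logistic model on the two stages'
#' linear predictors; the intercept is calibrated by bisection so the
#' expected prevalence over the drawn design matches the target within
#' 0.005. Fully deterministic given the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return list of class `uq_synth_cohort`: `cohort` (a `uq_cohort`),
#'   `truth` (list with `eta1`, `eta2`, `eta`, `subgroup` mask,
#'   coefficients and calibrated intercept) and `spec`.
#' @export
synth_cohort <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "uq_synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    x1c <- ar1_block(n, spec$n_cont1, spec$rho_x)
    x2c <- ar1_block(n, spec$n_cont2, spec$rho_x)
    p_bin1 <- rep_len(c(0.5, 0.3, 0.2, 0.4, 0.25, 0.6), spec$n_bin1)
    p_bin2 <- rep_len(c(0.35, 0.5, 0.2, 0.45, 0.3, 0.55), spec$n_bin2)
    x1b <- matrix(stats::rbinom(n * spec$n_bin1, 1L, rep(p_bin1, each = n)),
                  n, spec$n_bin1)
    x2b <- matrix(stats::rbinom(n * spec$n_bin2, 1L, rep(p_bin2, each = n)),
                  n, spec$n_bin2)
    x1 <- cbind(x1c, x1b)
    x2 <- cbind(x2c, x2b)
    colnames(x1) <- c(sprintf("s1_c%02d", seq_len(spec$n_cont1)),
                      sprintf("s1_b%02d", seq_len(spec$n_bin1)))
    colnames(x2) <- c(sprintf("s2_c%02d", seq_len(spec$n_cont2)),
                      sprintf("s2_b%02d", seq_len(spec$n_bin2)))

    eta1 <- drop(x1 %*% spec$beta1)
    eta2 <- drop(x2 %*% spec$beta2)
    eta2 <- eta2 - mean(eta2)

    med <- stats::median(eta1)
    subgroup <- rep(FALSE, n)
    if (spec$rho > 0) {
      k <- round(spec$rho * n)
      subgroup[order(abs(eta1 - med))[seq_len(k)]] <- TRUE
    }
    eta <- eta1
    eta[subgroup] <- med + spec$attenuation * (eta1[subgroup] - med) +
      eta2[subgroup]

    # bisection on the intercept against the expected prevalence
    lo <- -20; hi <- 20
    target <- spec$prevalence
    for (i in 1:200) {
      b0 <- (lo + hi) / 2
      prev <- mean(sigmoid(b0 + eta))
      if (abs(prev - target) < 0.005) break
      if (prev < target) lo <- b0 else hi <- b0
    }
    if (abs(prev - target) >= 0.01)
      stop("prevalence calibration failed to converge", call. = FALSE)
    y <- stats::rbinom(n, 1L, sigmoid(b0 + eta))

    df <- data.frame(x1, x2, response = y, check.names = FALSE)
    feats <- data.frame(
      name = c(colnames(x1), colnames(x2)),
      kind = c(rep("continuous", spec$n_cont1), rep("binary", spec$n_bin1),
               rep("continuous", spec$n_cont2), rep("binary", spec$n_bin2)),
      stage = c(rep(1L, ncol(x1)), rep(2L, ncol(x2))))
    schema <- feature_schema(feats, "response")
    cohort <- validate_cohort(df, schema)
    structure(list(cohort = cohort,
                   truth = list(eta1 = eta1, eta2 = eta2, eta = eta,
                                subgroup = subgroup, beta1 = spec$beta1,
                                beta2 = spec$beta2, intercept = b0),
                   spec = spec),
              class = "uq_synth_cohort")
  })
}

#' Write the small fixture suite used by the tests and examples
#'
#' Emits four CSV cohorts with schema YAMLs and a JSON manifest of seeds
#' and expected properties: a linearly separable toy (n = 40), a tie-heavy
#' cohort with coarsely discretized features, an ambiguous-subgroup cohort
#' (rho = 0.4), and a tiny imbalanced cohort that provokes single-class
#' slices.
#'
#' @param out_dir writable directory (created if absent).
#' @return invisibly, the manifest list.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(name, synth) {
    df <- synth$cohort$data
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 5))
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    write_schema(synth$cohort$schema, file.path(out_dir, paste0(name, ".yaml")))
  }

  separable <- synth_cohort(synth_spec(
    n = 40L, prevalence = 0.5, rho = 0, n_cont1 = 2L, n_bin1 = 0L,
    n_cont2 = 2L, n_bin2 = 0L, beta2 = c(0, 0), effect_size = 8,
    seed = 101L))
  write_one("separable_toy", separable)

  tie_heavy <- synth_cohort(synth_spec(
    n = 60L, prevalence = 0.5, rho = 0, n_cont1 = 2L, n_bin1 = 2L,
    n_cont2 = 2L, n_bin2 = 0L, effect_size = 0.8, seed = 102L))
  th <- tie_heavy$cohort$data
  cont <- grep("_c", names(th), value = TRUE)
  th[cont] <- lapply(th[cont], function(v) round(v))  # coarse grid -> ties
  utils::write.csv(th, file.path(out_dir, "tie_heavy.csv"), row.names = FALSE)
  write_schema(tie_heavy$cohort$schema, file.path(out_dir, "tie_heavy.yaml"))

  ambiguous <- synth_cohort(synth_spec(n = 120L, rho = 0.4, seed = 103L))
  write_one("ambiguous_subgroup", ambiguous)

  degenerate <- synth_cohort(synth_spec(
    n = 20L, prevalence = 0.12, rho = 0, n_cont1 = 2L, n_bin1 = 0L,
    n_cont2 = 2L, n_bin2 = 0L, seed = 104L))
  write_one("degenerate_slice", degenerate)

  manifest <- list(
    generator = "uqcascade synth_cohort",
    synthetic = TRUE,
    fixtures = list(
      separable_toy = list(seed = 101L, n = 40L,
                           expect = "stage-1 ensemble test AUC > 0.95"),
      tie_heavy = list(seed = 102L, n = 60L,
                       expect = "many tied scores; AUC uses midranks"),
      ambiguous_subgroup = list(seed = 103L, n = 120L, rho = 0.4,
                                expect = "higher p_std inside subgroup"),
      degenerate_slice = list(seed = 104L, n = 20L, prevalence = 0.12,
                              expect = "small strata provoke single-class slices")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
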