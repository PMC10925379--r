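test_that("pseudo-bootstrap subsets have size round(phi*n), no replacement, seed-determined", {
  spec <- ensemble_spec(3L, 1.0, seed = 9)
  subs <- draw_pseudo_bootstrap(10L, spec)
  expect_length(subs, 3L)
  for (s in subs) expect_identical(s, 1:10)  # phi = 1 limit

  spec95 <- ensemble_spec(25L, 0.95, seed = 9)
  subs95 <- draw_pseudo_bootstrap(100L, spec95)
  expect_true(all(lengths(subs95) == 95L))
  expect_true(all(vapply(subs95, anyDuplicated, 0L) == 0L))
  expect_identical(draw_pseudo_bootstrap(100L, spec95), subs95)
  expect_false(identical(subs95[[1]], subs95[[2]]))

  expect_error(draw_pseudo_bootstrap(2L, ensemble_spec(2L, 0.5)), "below 2")
})

test_that("large lambda shrinks slopes to zero leaving the class prevalence", {
  set.seed(3)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, 0.7)
  fit <- fit_base(x, y, base_learner_spec(alpha = 0.5, lambda = 50))
  expect_true(all(abs(fit$beta) < 1e-8))
  expect_equal(unique(round(predict(fit, x), 6)), round(mean(y), 6))
})

test_that("a separating feature gives probabilities monotone in that feature", {
  x <- matrix(seq(-2, 2, length.out = 40), ncol = 1,
              dimnames = list(NULL, "z"))
  y <- as.numeric(x[, 1] > 0)
  fit <- fit_base(x, y, base_learner_spec(alpha = 0.5, lambda = 0.01))
  p <- predict(fit, x)
  expect_true(all(diff(p) > 0))
  expect_error(fit_base(x, rep(1, 40)), "single class")
})

test_that("ridge logistic fit matches a generic convex optimizer", {
  set.seed(11)
  x <- scale(matrix(rnorm(120), 60, 2))
  colnames(x) <- c("u", "v")
  y <- rbinom(60, 1, plogis(x[, 1] - 0.5 * x[, 2]))
  fit <- fit_base(x, y, base_learner_spec(alpha = 0, lambda = 0.1))
  oracle <- enet_logistic_optim(x, y, alpha = 0, lambda = 0.1)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-4)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-4)
})

test_that("unpenalized fit agrees with maximum-likelihood logistic regression", {
  set.seed(12)
  x <- scale(matrix(rnorm(300), 150, 2))
  colnames(x) <- c("u", "v")
  y <- rbinom(150, 1, plogis(0.8 * x[, 1]))
  fit <- fit_base(x, y, base_learner_spec(alpha = 0.5, lambda = 0))
  ml <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ml)[-1]), tolerance = 1e-4)
})

test_that("ensemble prediction aggregates member probabilities as mean and sample sd", {
  # two members with hand-built coefficients: probs 0.4 and 0.6 everywhere
  mk <- function(b0) structure(list(intercept = b0, beta = c(z = 0),
                                    spec = base_learner_spec(),
                                    converged = TRUE), class = "uq_base_fit")
  ens <- structure(list(
    members = list(mk(qlogis(0.4)), mk(qlogis(0.6))),
    preprocess = structure(list(center = c(z = 0), scale = c(z = 1),
                                features = "z", dropped = character(0),
                                spatial_sign = FALSE), class = "uq_preproc"),
    features = "z", outcome = "y",
    espec = ensemble_spec(2L), bspec = base_learner_spec(), n_train = 10L),
    class = "uq_ensemble")
  pr <- predict(ens, data.frame(z = c(1, 2, 3)))
  expect_equal(pr$mean, rep(0.5, 3))
  expect_equal(pr$std, rep(sd(c(0.4, 0.6)), 3))  # 0.1414...
  expect_true(all(pr$mean >= apply(pr$members, 1, min) &
                    pr$mean <= apply(pr$members, 1, max)))
})

test_that("fit_ensemble trains B members on phi-subsets sharing one preprocessing", {
  sc <- synth_cohort(synth_spec(n = 120, rho = 0, seed = 5))
  df <- sc$cohort$data
  feats <- grep("^s1", names(df), value = TRUE)
  ens <- fit_ensemble(df, feats, "response",
                      ensemble_spec(25L, 0.95, seed = 3))
  expect_length(ens$members, 25L)
  expect_s3_class(ens$preprocess, "uq_preproc")
  pr <- predict(ens, df)
  expect_true(all(pr$std >= 0))
  expect_true(all(pr$mean > 0 & pr$mean < 1))
  # B = 1: zero predictive sd, flagged at fit time
  expect_warning(e1 <- fit_ensemble(df, feats, "response",
                                    ensemble_spec(1L, 1.0, seed = 3)),
                 "single-member")
  expect_equal(predict(e1, df)$std, rep(0, nrow(df)))
  # phi = 1 duplicates the training subset: members identical, p_std = 0
  e2 <- fit_ensemble(df, feats, "response", ensemble_spec(3L, 1.0, seed = 3))
  expect_equal(predict(e2, df)$std, rep(0, nrow(df)))
})

test_that("predictive sd shrinks as the sample fraction approaches one", {
  sc <- synth_cohort(synth_spec(n = 150, rho = 0, seed = 8))
  df <- sc$cohort$data
  feats <- grep("^s1", names(df), value = TRUE)
  mean_std <- vapply(c(0.6, 0.8, 1.0), function(phi) {
    ens <- fit_ensemble(df, feats, "response",
                        ensemble_spec(10L, phi, seed = 4))
    mean(predict(ens, df)$std)
  }, 0)
  expect_true(all(diff(mean_std) < 0))
  expect_equal(mean_std[3], 0)
})

test_that("RFE keeps informative features and discards pure noise", {
  set.seed(21)
  n <- 1200
  df <- data.frame(signal = rnorm(n), noise = rnorm(n))
  df$response <- rbinom(n, 1, plogis(2 * df$signal))
  sel <- select_features_rfe(df, c("signal", "noise"), "response",
                             base_learner_spec(0.5, 0.01), seed = 2)
  expect_identical(as.character(sel), "signal")

  expect_identical(select_features_rfe(df, "signal", "response"), "signal")

  df$copy <- df$signal
  sel2 <- select_features_rfe(df, c("signal", "copy", "noise"), "response",
                              base_learner_spec(0.5, 0.01), seed = 2)
  expect_true(any(c("signal", "copy") %in% sel2))
})

test_that("ensemble tuning returns the grid point with top inner-CV AUC", {
  sc <- synth_cohort(synth_spec(n = 120, rho = 0, seed = 6))
  df <- sc$cohort$data
  feats <- grep("^s1", names(df), value = TRUE)
  one <- tune_ensemble(df, feats, "response",
                       grid = list(n_models = 5, sample_fraction = 0.9),
                       inner_folds = 3L, seed = 1)
  expect_equal(one$espec$n_models, 5L)
  expect_equal(one$espec$sample_fraction, 0.9)

  got <- tune_ensemble(df, feats, "response",
                       grid = list(n_models = c(4, 6),
                                   sample_fraction = c(0.8, 0.95)),
                       inner_folds = 3L, seed = 1)
  expect_true(got$espec$n_models %in% c(4L, 6L))
  expect_true(got$espec$sample_fraction %in% c(0.8, 0.95))
  expect_equal(nrow(got$results), 4L)
  expect_error(tune_ensemble(df, feats, "response", grid = list()), "empty")
})

test_that("fitted ensembles serialize to JSON and back without changing predictions", {
  sc <- synth_cohort(synth_spec(n = 80, rho = 0, seed = 13))
  df <- sc$cohort$data
  ens <- fit_ensemble(df, grep("^s1", names(df), value = TRUE), "response",
                      ensemble_spec(4L, 0.9, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_json(ens, path)
  ens2 <- read_ensemble_json(path)
  expect_equal(predict(ens2, df)$mean, predict(ens, df)$mean, tolerance = 1e-12)
})
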