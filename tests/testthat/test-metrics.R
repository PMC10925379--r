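test_that("roc_auc equals the Mann–Whitney concordance on hand cases", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1), c(0.5, 0.5)), 0.5)
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.2, 0.3, 0.4, 0.5)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("roc_auc matches the brute-force all-pairs oracle with ties", {
  withr::with_seed(101, {
    for (i in 1:100) {
      n <- sample(4:200, 1)
      y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
      s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # tie-heavy
      expect_identical(roc_auc(y, s), auc_bruteforce(y, s))
    }
  })
})

test_that("roc_auc complements under score negation and agrees with pROC", {
  withr::with_seed(55, {
    y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
    s <- rnorm(60)
    expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1)
    expect_equal(roc_auc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  })
})

test_that("confusion metrics count the standard way at the 0.5 cutoff", {
  m <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.2, 0.1, 0.1))
  expect_equal(unname(m), c(0.75, 0.5, 1.0))
  m2 <- confusion_metrics(c(1, 0), c(0.8, 0.7))
  expect_equal(unname(m2["sensitivity"]), 1)
  expect_equal(unname(m2["specificity"]), 0)
  m3 <- confusion_metrics(c(1, 0), c(0.9, 0.1))
  expect_equal(unname(m3), c(1, 1, 1))
  m4 <- confusion_metrics(c(1, 1), c(0.9, 0.2))
  expect_true(is.na(m4["specificity"]))
})

test_that("DeLong test handles identical models and is sign-symmetric", {
  withr::with_seed(77, {
    y <- rep(c(0, 1), 15)
    a <- plogis(rnorm(30) + y)
    same <- delong_test(y, a, a)
    expect_equal(same$p_value, 1)
    expect_true(same$degenerate)
    expect_equal(same$delta_auc, 0)

    b <- plogis(rnorm(30))
    ab <- delong_test(y, a, b)
    ba <- delong_test(y, b, a)
    expect_equal(ab$delta_auc, -ba$delta_auc)
    expect_equal(ab$p_value, ba$p_value)
    expect_true(ab$p_value >= 0 && ab$p_value <= 1)
    expect_true(ab$ci_a[1] <= ab$auc_a && ab$auc_a <= ab$ci_a[2])
  })
})

test_that("DeLong p-value is close to a stratified bootstrap of the AUC difference", {
  withr::with_seed(42, {
    y <- rep(c(0, 1), 10)
    a <- plogis(rnorm(20) + 1.5 * y)
    b <- plogis(rnorm(20) + 0.3 * y)
    dl <- delong_test(y, a, b)
    boot <- delta_auc_bootstrap_p(y, a, b, reps = 4000L, seed = 1)
    expect_lt(abs(dl$p_value - boot), 0.05)
  })
})

test_that("McNemar switches between exact binomial and corrected chi-square", {
  sym <- mcnemar_test(c(rep(TRUE, 5), rep(FALSE, 5)),
                      c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$method, "exact")

  none <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(none$p_value, 1)
  expect_true(none$degenerate)

  onesided <- mcnemar_test(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(onesided$p_value, 2 * 0.5^10)  # closed form

  big <- mcnemar_test(c(rep(TRUE, 20), rep(FALSE, 10)),
                      c(rep(FALSE, 20), rep(TRUE, 10)))
  expect_equal(big$method, "chi-square")
  ref <- stats::mcnemar.test(matrix(c(0, 10, 20, 0), 2), correct = TRUE)
  expect_equal(big$p_value, ref$p.value)
})

test_that("permutation importance is zero for ignored features, largest for the driver", {
  sc <- synth_cohort(synth_spec(n = 200, rho = 0, seed = 31,
                                n_cont1 = 3, n_bin1 = 0, n_cont2 = 1,
                                n_bin2 = 0, beta1 = c(2, 0, 0), beta2 = 0))
  df <- sc$cohort$data
  feats <- grep("^s1", names(df), value = TRUE)
  ens <- fit_ensemble(df, feats, "response", ensemble_spec(5L, 0.9, seed = 1),
                      base_learner_spec(0.5, 0.01))
  imp <- permutation_importance(ens, df, "response", n_permutations = 5,
                                seed = 2)
  expect_equal(names(imp)[1], "s1_c01")
  expect_gt(imp["s1_c01"], 5 * max(abs(imp[c("s1_c02", "s1_c03")])))

  # an ensemble whose members ignore every feature has exactly zero importance
  ens0 <- fit_ensemble(df, feats, "response", ensemble_spec(3L, 0.9, seed = 1),
                       base_learner_spec(0.5, lambda = 50))
  imp0 <- permutation_importance(ens0, df, "response", n_permutations = 3,
                                 seed = 2)
  expect_true(all(imp0 == 0))
})

test_that("baseline table summarizes by kind and reproduces marginal arithmetic", {
  n <- 218
  y <- rep(c(1, 0), c(121, 97))
  df <- data.frame(
    male = rep(c(1, 0), c(133, 85)),
    age = c(rnorm(121, 60, 10), rnorm(97, 63, 10)),
    response = y)
  sch <- feature_schema(data.frame(name = c("male", "age"),
                                   kind = c("binary", "continuous"),
                                   stage = c(1, 2)), "response")
  co <- validate_cohort(df, sch)
  tab <- baseline_table(co)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$test, c("chi_square", "welch_t"))
  out <- attr(tab, "outcome")
  expect_equal(unname(out["responder_pct"]), 100 * 121 / 218)
  expect_equal(unname(out["non_responder_pct"]), 100 * 97 / 218)
  cs <- cohort_summary(y, male = df$male)
  expect_equal(unname(cs["male_pct"]), 100 * 133 / 218)

  # identical group distributions: Welch t on equal samples gives p ~ 1
  df2 <- data.frame(x = rep(c(1.2, 3.4, 5.6), 2),
                    response = rep(c(0, 1), each = 3))
  sch2 <- feature_schema(data.frame(name = "x", kind = "continuous",
                                    stage = 1), "response")
  tab2 <- baseline_table(validate_cohort(df2, sch2))
  expect_equal(tab2$p_value, 1)

  # balanced 2x2 table: chi-square statistic 0, p = 1
  df3 <- data.frame(b = rep(c(0, 1, 0, 1), each = 10),
                    response = rep(c(0, 0, 1, 1), each = 10))
  sch3 <- feature_schema(data.frame(name = "b", kind = "binary", stage = 1),
                         "response")
  tab3 <- baseline_table(validate_cohort(df3, sch3))
  expect_equal(tab3$p_value, 1)
})
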