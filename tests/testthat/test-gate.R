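test_that("the gate escalates on high disagreement OR near-midway means", {
  pol <- gate_policy(0.15, 0.04)  # thresholds as in a tuned fold
  g <- gate_decision(list(mean = c(0.90, 0.52, 0.90),
                          std = c(0.01, 0.01, 0.20)), pol)
  expect_identical(g$needs_stage2, c(FALSE, TRUE, TRUE))
  expect_identical(as.character(g$reason),
                   c("none", "near_midway", "high_std"))
  g2 <- gate_decision(list(mean = 0.51, std = 0.3), pol)
  expect_identical(as.character(g2$reason), "both")
  expect_error(gate_policy(-0.1, 0.1), ">= 0")
  expect_error(gate_policy(0.1, 0.7))
})

test_that("scaling weight obeys its boundary and monotonicity contract", {
  for (form in c("saturating", "power")) {
    expect_equal(scaling_weight_fn(1, 0.5, form), 1)
    expect_equal(scaling_weight_fn(1, 9, form), 1)
    expect_equal(scaling_weight_fn(0, 3, form), 0)
    f <- seq(0, 1, by = 0.05)
    for (s in c(0.5, 1, 4, 9))
      expect_true(all(diff(scaling_weight_fn(f, s, form)) >= 0))
    for (fv in c(0.2, 0.5, 0.8))
      expect_true(all(diff(scaling_weight_fn(fv, c(0.5, 1, 3, 6, 9), form)) >= 0))
  }
  expect_equal(scaling_weight_fn(0.25, 0.5, "power"), 0.0625)  # 0.25^2
  expect_error(scaling_weight_fn(1.2, 1), "\\[0, 1\\]")
  expect_error(scaling_weight_fn(0.5, 12), "\\[0.5, 9\\]")
})

test_that("scaled weighted AUC equals AUC times the stage-1 weight", {
  y <- c(0, 0, 1, 1)
  p <- c(0.1, 0.6, 0.4, 0.9)   # AUC 0.75
  expect_equal(scaled_weighted_auc(y, p, f = 1, s = 3), 0.75)
  expect_equal(scaled_weighted_auc(y, p, f = 0, s = 3), 0)
  # both forms coincide at s = 1: w(0.5) = 0.5
  p2 <- c(0.1, 0.2, 0.8, 0.9)  # AUC 0.8... with these labels AUC = 1
  expect_equal(scaled_weighted_auc(y, p, f = 0.5, s = 1), 0.75 * 0.5)
  expect_equal(scaled_weighted_auc(y, p, f = 0.5, s = 1, form = "power"),
               0.75 * 0.5)
  expect_error(scaled_weighted_auc(c(1, 1), c(0.2, 0.3), 1, 1), "single class")
})

test_that("objective never exceeds plain AUC, equal only when nobody escalates", {
  y <- rep(c(0, 1), 10)
  set.seed(2)
  p <- runif(20)
  auc <- roc_auc(y, p)
  for (form in c("saturating", "power"))
    for (f in seq(0, 0.95, by = 0.05))
      for (s in c(0.5, 2, 9))
        expect_lt(scaled_weighted_auc(y, p, f, s, form), auc)
  expect_equal(scaled_weighted_auc(y, p, 1, 0.5), auc)
})

test_that("escalated fraction is monotone in both thresholds", {
  set.seed(5)
  pred <- list(mean = runif(200), std = runif(200, 0, 0.3))
  esc_frac <- function(ts, tm)
    mean(gate_decision(pred, gate_policy(ts, tm))$needs_stage2)
  for (tm in c(0, 0.1, 0.3)) {
    esc <- vapply(seq(0, 0.3, by = 0.02), esc_frac, 0, tm = tm)
    expect_true(all(diff(esc) <= 0))  # raising tau_sigma escalates fewer
  }
  for (ts in c(0.05, 0.15)) {
    esc <- vapply(seq(0, 0.5, by = 0.05), function(tm) esc_frac(ts, tm), 0)
    expect_true(all(diff(esc) >= 0))  # widening the midway band escalates more
  }
})

test_that("threshold tuning matches an exhaustive independent grid search", {
  fx <- fit_toy_ensembles()
  val <- fx$data[1:60, ]
  y <- val$response
  std_grid <- c(0.005, 0.01, 0.02)
  mid_grid <- c(0.02, 0.06, 0.10)
  s <- 4
  pol <- tune_thresholds(fx$ens1, fx$ens2, val, "response", s,
                         std_grid = std_grid, mid_grid = mid_grid)
  # oracle: enumerate the grid from scratch with the public pieces
  p1 <- predict(fx$ens1, val); p2 <- predict(fx$ens2, val)
  best <- NULL
  for (tm in mid_grid) for (ts in std_grid) {  # note: different loop order
    g <- gate_decision(p1, gate_policy(ts, tm))
    prob <- ifelse(g$needs_stage2, p2$mean, p1$mean)
    f <- mean(!g$needs_stage2)
    obj <- scaled_weighted_auc(y, prob, f, s)
    better <- is.null(best) || obj > best$obj ||
      (obj == best$obj && (f > best$f || (f == best$f && ts > best$ts)))
    if (better) best <- list(obj = obj, f = f, ts = ts, tm = tm)
  }
  expect_equal(pol$std_threshold, best$ts)
  expect_equal(pol$midway_threshold, best$tm)
  expect_equal(attr(pol, "objective"), best$obj)
  expect_true(pol$std_threshold %in% std_grid)
  expect_true(pol$midway_threshold %in% mid_grid)
})

test_that("identical ensembles make the tuner escalate nobody (tie-break)", {
  fx <- fit_toy_ensembles()
  val <- fx$data[1:60, ]
  pol <- tune_thresholds(fx$ens1, fx$ens1, val, "response", s = 2,
                         std_grid = c(0.01, 1), mid_grid = c(0, 0.1))
  expect_equal(attr(pol, "f"), 1)
  expect_equal(pol$midway_threshold, 0)

  # scaling selection ties also prefer fewer escalations
  c_none <- gate_policy(1, 0, scaling_weight = 1)
  c_some <- gate_policy(0.001, 0.2, scaling_weight = 2)
  sel <- select_scaling(fx$ens1, fx$ens1, val, "response",
                        list(c_some, c_none))
  expect_equal(sel$scaling_weight, 1)
  sel1 <- select_scaling(fx$ens1, fx$ens2, val, "response", list(c_some))
  expect_equal(sel1$scaling_weight, 2)
  expect_error(select_scaling(fx$ens1, fx$ens2, val, "response", list()),
               "no candidate")
})

test_that("cascade boundary identities: gate closed = Ensemble 1, open = Ensemble 2", {
  fx <- fit_toy_ensembles()
  newdata <- fx$data[101:160, ]
  p1 <- predict(fx$ens1, newdata)$mean
  p2 <- predict(fx$ens2, newdata)$mean
  closed <- predict_cascade(fx$ens1, fx$ens2, gate_policy(1e9, 0), newdata)
  expect_identical(closed$final_prob, p1)
  expect_equal(attr(closed, "fraction_stage1"), 1)
  open <- predict_cascade(fx$ens1, fx$ens2, gate_policy(0, 0.5), newdata)
  expect_identical(open$final_prob, p2)
  expect_equal(attr(open, "fraction_stage1"), 0)

  # a mid-quantile policy escalates a strict subset; audit the rule per row
  pr1 <- predict(fx$ens1, newdata)
  tau_s <- unname(quantile(pr1$std, 0.5))
  mixed <- predict_cascade(fx$ens1, fx$ens2, gate_policy(tau_s, 0.05), newdata)
  f <- attr(mixed, "fraction_stage1")
  expect_true(f > 0 && f < 1)
  esc <- pr1$std > tau_s | abs(pr1$mean - 0.5) < 0.05
  expect_identical(mixed$stage_used == 2L, esc)
  expect_equal(f, mean(!esc))
})

test_that("escalated rows missing stage-2 features raise an acquisition error", {
  fx <- fit_toy_ensembles()
  newdata <- fx$data[101:120, ]
  s2cols <- grep("^s2", names(newdata), value = TRUE)
  newdata[, s2cols] <- NA_real_
  expect_error(predict_cascade(fx$ens1, fx$ens2, gate_policy(0, 0.5), newdata),
               "acquisition required")
})

test_that("gate policies serialize to JSON and back", {
  pol <- gate_policy(0.15, 0.04, 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_policy_json(pol, path)
  expect_equal(read_policy_json(path), pol, ignore_attr = TRUE)
})
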