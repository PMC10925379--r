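#' Define a gate policy for the cascade
#'
#' A patient's first-stage prediction is escalated to the second stage when
#' its ensemble standard deviation exceeds `std_threshold` (the prediction
#' is unstable) or its mean probability lies within `midway_threshold` of
#' the 0.5 decision midpoint (the prediction is equivocal). The
#' `scaling_weight` records the scaling parameter of the tuning objective
#' under which the thresholds were learned.
#'
#' @param std_threshold tau_sigma >= 0.
#' @param midway_threshold tau_m in \[0, 0.5\].
#' @param scaling_weight s in \[0.5, 9\] (NA when not tuned).
#' @return list of class `uq_gate_policy`.
#' @export
gate_policy <- function(std_threshold, midway_threshold, scaling_weight = NA) {
  stopifnot(std_threshold >= 0,
            midway_threshold >= 0, midway_threshold <= 0.5)
  if (!is.na(scaling_weight))
    stopifnot(scaling_weight >= 0.5, scaling_weight <= 9)
  structure(list(std_threshold = std_threshold,
                 midway_threshold = midway_threshold,
                 scaling_weight = scaling_weight),
            class = "uq_gate_policy")
}

#' @export
print.uq_gate_policy <- function(x, ...) {
  cat(sprintf("Gate policy: tau_sigma = %.3g, tau_m = %.3g, s = %s\n",
              x$std_threshold, x$midway_threshold,
              if (is.na(x$scaling_weight)) "untuned" else
                format(x$scaling_weight)))
  invisible(x)
}

#' Apply the gate rule to uncertainty predictions
#'
#' Escalation fires iff `p_std > tau_sigma` OR `|p_mean - 0.5| < tau_m`
#' (strict inequalities); the reason records which clause fired.
#'
#' @param pred a `uq_prediction` (or list with `mean` and `std`).
#' @param policy a [gate_policy()].
#' @return data.frame with logical `needs_stage2` and factor `reason`
#'   (`none`, `high_std`, `near_midway`, `both`).
#' @export
gate_decision <- function(pred, policy) {
  stopifnot(inherits(policy, "uq_gate_policy"))
  high_std <- pred$std > policy$std_threshold
  near_mid <- abs(pred$mean - 0.5) < policy$midway_threshold
  reason <- rep("none", length(high_std))
  reason[high_std & !near_mid] <- "high_std"
  reason[!high_std & near_mid] <- "near_midway"
  reason[high_std & near_mid] <- "both"
  data.frame(needs_stage2 = high_std | near_mid,
             reason = factor(reason,
                             levels = c("none", "high_std", "near_midway", "both")))
}

#' Scaling weight of the gate-tuning objective
#'
#' Maps the fraction `f` of patients resolved at stage 1 to a
#' multiplicative weight in \[0, 1\], monotone nondecreasing in both `f`
#' and the scaling parameter `s`, with `w(0; s) = 0` and `w(1; s) = 1`.
#' Two forms are provided:
#'
#' * `"saturating"` (default): `w = 1 - (1 - f)^s`. Near 1 for moderate
#'   `f` and collapsing only as `f -> 0`, so the objective mainly forbids
#'   *universal* escalation; small `s` enforces the stage-1 budget
#'   strongly, large `s` barely at all.
#' * `"power"`: `w = f^(1/s)`, a steeper penalty that discourages any
#'   escalation unless the AUC gain is large.
#'
#' @param f fraction kept at stage 1, in \[0, 1\].
#' @param s scaling parameter in \[0.5, 9\].
#' @param form weight shape, `"saturating"` or `"power"`.
#' @return weight in \[0, 1\].
#' @export
scaling_weight_fn <- function(f, s, form = c("saturating", "power")) {
  form <- match.arg(form)
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  if (any(s < 0.5 | s > 9)) stop("s must lie in [0.5, 9]", call. = FALSE)
  switch(form, saturating = 1 - (1 - f)^s, power = f^(1 / s))
}

#' Scaled weighted AUC: the gate-tuning objective
#'
#' Plain AUC of the cascade probabilities multiplied by
#' [scaling_weight_fn()] of the fraction resolved at stage 1 — rewarding
#' discrimination while penalizing universal escalation.
#'
#' @param labels binary outcome vector, both classes present.
#' @param cascade_probs final cascade probabilities.
#' @param f fraction of patients kept at stage 1.
#' @param s scaling parameter.
#' @param form weight shape, see [scaling_weight_fn()].
#' @return objective value in \[0, 1\], never above the plain AUC.
#' @export
scaled_weighted_auc <- function(labels, cascade_probs, f, s,
                                form = c("saturating", "power")) {
  roc_auc(labels, cascade_probs) * scaling_weight_fn(f, s, match.arg(form))
}

# Cascade probabilities and stage-1 fraction from precomputed ensemble
# predictions under one policy; the workhorse of the grid searches.
cascade_from_preds <- function(pred1, pred2, policy) {
  g <- gate_decision(pred1, policy)
  prob <- ifelse(g$needs_stage2, pred2$mean, pred1$mean)
  list(prob = prob, f = mean(!g$needs_stage2),
       stage_used = ifelse(g$needs_stage2, 2L, 1L), reason = g$reason)
}

#' Tune the gate thresholds on the first validation slice
#'
#' Exhaustive grid search over (tau_sigma, tau_m) maximizing the scaled
#' weighted AUC of the cascade at a fixed scaling parameter `s`. Ties are
#' broken toward a larger stage-1 fraction (fewer escalations), then a
#' larger tau_sigma.
#'
#' @param ens1,ens2 fitted `uq_ensemble`s sharing a training partition.
#' @param validation data.frame of held-out validation-1 rows (disjoint
#'   from training).
#' @param outcome binary outcome column name.
#' @param s scaling parameter for the objective.
#' @param std_grid,mid_grid candidate threshold grids.
#' @param form weight shape, see [scaling_weight_fn()].
#' @return a [gate_policy()] with attributes `objective` and `f`.
#' @export
tune_thresholds <- function(ens1, ens2, validation, outcome, s,
                            std_grid = seq(0.01, 0.20, by = 0.01),
                            mid_grid = seq(0.02, 0.10, by = 0.01),
                            form = c("saturating", "power")) {
  form <- match.arg(form)
  y <- validation[[outcome]]
  if (length(unique(y)) < 2L)
    stop("validation slice has a single outcome class", call. = FALSE)
  pred1 <- predict(ens1, validation)
  pred2 <- predict(ens2, validation)
  grid <- expand.grid(std = std_grid, mid = mid_grid)
  res <- vapply(seq_len(nrow(grid)), function(i) {
    cs <- cascade_from_preds(pred1, pred2,
                             gate_policy(grid$std[i], grid$mid[i], s))
    c(obj = roc_auc(y, cs$prob) * scaling_weight_fn(cs$f, s, form), f = cs$f)
  }, c(obj = 0, f = 0))
  ord <- order(-res["obj", ], -res["f", ], -grid$std)
  i <- ord[1L]
  out <- gate_policy(grid$std[i], grid$mid[i], s)
  attr(out, "objective") <- unname(res["obj", i])
  attr(out, "f") <- unname(res["f", i])
  out
}

#' Select the scaling parameter on the second validation slice
#'
#' Among threshold policies learned under different scaling parameters,
#' returns the one whose cascade achieves the highest *plain* AUC on the
#' second validation slice; ties go to the candidate keeping more patients
#' at stage 1 there.
#'
#' @param ens1,ens2 fitted `uq_ensemble`s.
#' @param validation data.frame of validation-2 rows (disjoint from
#'   training and validation 1).
#' @param outcome binary outcome column name.
#' @param candidates non-empty list of [gate_policy()] objects.
#' @return the winning `uq_gate_policy`, with attributes `val2_auc` and
#'   `val2_f`.
#' @export
select_scaling <- function(ens1, ens2, validation, outcome, candidates) {
  if (!length(candidates)) stop("no candidate policies", call. = FALSE)
  y <- validation[[outcome]]
  if (length(unique(y)) < 2L)
    stop("validation slice has a single outcome class", call. = FALSE)
  pred1 <- predict(ens1, validation)
  pred2 <- predict(ens2, validation)
  res <- vapply(candidates, function(pol) {
    cs <- cascade_from_preds(pred1, pred2, pol)
    c(auc = roc_auc(y, cs$prob), f = cs$f)
  }, c(auc = 0, f = 0))
  ord <- order(-res["auc", ], -res["f", ])
  i <- ord[1L]
  out <- candidates[[i]]
  attr(out, "val2_auc") <- unname(res["auc", i])
  attr(out, "val2_f") <- unname(res["f", i])
  out
}

#' Cascade predictions for a cohort under a fixed policy
#'
#' Rows passing the gate keep Ensemble 1's mean probability (stage 1);
#' escalated rows are replaced by Ensemble 2's (stage 2).
#'
#' @param ens1,ens2 fitted `uq_ensemble`s.
#' @param policy a [gate_policy()].
#' @param newdata data.frame with stage-1 features for all rows and stage-2
#'   features for escalated rows; escalated rows with any missing stage-2
#'   feature raise an acquisition-required error naming them.
#' @return data.frame of class `uq_cascade_prediction`: `final_prob`,
#'   `stage_used`, `reason`, with attribute `fraction_stage1`.
#' @export
predict_cascade <- function(ens1, ens2, policy, newdata) {
  pred1 <- predict(ens1, newdata)
  g <- gate_decision(pred1, policy)
  prob <- pred1$mean
  if (any(g$needs_stage2)) {
    esc <- which(g$needs_stage2)
    s2 <- newdata[esc, , drop = FALSE]
    s2feats <- intersect(ens2$features, names(newdata))
    miss <- esc[apply(is.na(s2[, s2feats, drop = FALSE]), 1L, any)]
    if (length(setdiff(ens2$features, names(newdata))) || length(miss))
      stop("stage-2 acquisition required for escalated patient(s): ",
           paste(if (length(miss)) miss else "all", collapse = ", "),
           call. = FALSE)
    prob[esc] <- predict(ens2, s2)$mean
  }
  out <- data.frame(final_prob = prob,
                    stage_used = ifelse(g$needs_stage2, 2L, 1L),
                    reason = g$reason)
  attr(out, "fraction_stage1") <- mean(!g$needs_stage2)
  class(out) <- c("uq_cascade_prediction", "data.frame")
  out
}
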