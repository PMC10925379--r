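#' Area under the ROC curve (Mann–Whitney form)
#'
#' The exact concordance statistic: the fraction of (positive, negative)
#' pairs in which the positive scores higher, ties counting 1/2. Computed
#' via midranks in O(n log n).
#'
#' @param labels binary vector (0/1), both classes present.
#' @param scores numeric score/probability vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Accuracy, sensitivity and specificity at a probability cutoff
#'
#' Predicted positive iff `prob >= cutoff` (default 0.5). With a
#' single-class label vector the undefined rate is returned as `NA`.
#'
#' @param labels binary vector (0/1).
#' @param probs probability vector.
#' @param cutoff classification cutoff.
#' @return named numeric vector: accuracy, sensitivity, specificity.
#' @export
confusion_metrics <- function(labels, probs, cutoff = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(probs >= cutoff)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# AUC/accuracy/sensitivity/specificity in one call.
classification_metrics <- function(labels, probs, cutoff = 0.5) {
  auc <- if (length(unique(labels)) < 2L) NA_real_ else roc_auc(labels, probs)
  c(auc = auc, confusion_metrics(labels, probs, cutoff))
}

#' DeLong test comparing two correlated AUCs
#'
#' Wraps the DeLong placement-covariance estimator (via \pkg{pROC}) for
#' paired scores on the same patients: two-sided p-value for the AUC
#' difference and DeLong 95% confidence intervals on each AUC. When the
#' variance of the difference degenerates to zero (e.g. identical scores),
#' the p-value is reported as 1 with `degenerate = TRUE`.
#'
#' @param labels binary outcome vector (0/1).
#' @param scores_a,scores_b paired score vectors.
#' @return list of class `uq_comparison`: `test`, `statistic`, `p_value`,
#'   `delta_auc`, `auc_a`, `auc_b`, `ci_a`, `ci_b`, `degenerate`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  stopifnot(length(labels) == length(scores_a),
            length(labels) == length(scores_b))
  if (length(unique(labels)) < 2L)
    stop("DeLong test undefined: single-class labels", call. = FALSE)
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  delta <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  tst <- tryCatch(
    suppressWarnings(pROC::roc.test(ra, rb, method = "delong", paired = TRUE)),
    error = function(e) NULL)
  stat <- if (!is.null(tst)) unname(tst$statistic) else NA_real_
  p <- if (!is.null(tst)) unname(tst$p.value) else NaN
  degenerate <- !is.finite(p) || all(scores_a == scores_b)
  if (degenerate) { p <- 1; stat <- 0 }
  ci <- function(r) tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  structure(list(test = "delong_auc", statistic = stat, p_value = p,
                 delta_auc = delta,
                 auc_a = as.numeric(pROC::auc(ra)),
                 auc_b = as.numeric(pROC::auc(rb)),
                 ci_a = ci(ra), ci_b = ci(rb), degenerate = degenerate),
            class = "uq_comparison")
}

#' McNemar test on paired per-patient correctness
#'
#' Takes paired indicators of whether each model classified a patient
#' correctly (restricted by the caller to the relevant class: positives for
#' sensitivity, negatives for specificity). Uses the exact binomial test on
#' the discordant pairs when they number fewer than `exact_limit`, the
#' continuity-corrected chi-square otherwise. Zero discordant pairs give
#' p = 1 with `degenerate = TRUE`.
#'
#' @param correct_a,correct_b logical/0-1 vectors of equal length.
#' @param exact_limit switch point between exact and asymptotic test.
#' @return list of class `uq_comparison`: `test`, `statistic` (discordant
#'   counts b, c for the exact branch; chi-square otherwise), `p_value`,
#'   `method`, `degenerate`.
#' @export
mcnemar_test <- function(correct_a, correct_b, exact_limit = 25L) {
  a <- as.logical(correct_a); bv <- as.logical(correct_b)
  stopifnot(length(a) == length(bv))
  b <- sum(a & !bv)   # a right, b wrong
  cc <- sum(!a & bv)  # a wrong, b right
  if (b + cc == 0L) {
    return(structure(list(test = "mcnemar", statistic = c(b = b, c = cc),
                          p_value = 1, method = "degenerate",
                          degenerate = TRUE),
                     class = "uq_comparison"))
  }
  if (b + cc < exact_limit) {
    p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
    structure(list(test = "mcnemar", statistic = c(b = b, c = cc),
                   p_value = p, method = "exact", degenerate = FALSE),
              class = "uq_comparison")
  } else {
    m <- matrix(c(0, cc, b, 0), 2L)  # only discordant cells matter
    ht <- stats::mcnemar.test(m, correct = TRUE)
    structure(list(test = "mcnemar", statistic = unname(ht$statistic),
                   p_value = ht$p.value, method = "chi-square",
                   degenerate = FALSE),
              class = "uq_comparison")
  }
}

#' @export
print.uq_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g%s\n", x$test, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Baseline characteristics table with group comparisons
#'
#' Summarizes every feature overall and by outcome group: categorical and
#' binary features as count (percentage) with a chi-square test of
#' independence, continuous features as mean ± sd with a Welch two-sample
#' t-test. An expected cell count of zero flags the chi-square row.
#'
#' @param cohort a `uq_cohort` (or data.frame plus `schema`).
#' @param schema schema when `cohort` is a plain data.frame.
#' @return data.frame of class `uq_baseline`, one row per feature, with
#'   summaries for the overall cohort and each outcome group, the test
#'   used, the p-value, and a `flag` column.
#' @export
baseline_table <- function(cohort, schema = NULL) {
  if (inherits(cohort, "uq_cohort")) { schema <- cohort$schema; df <- cohort$data }
  else df <- as.data.frame(cohort)
  stopifnot(inherits(schema, "uq_schema"))
  y <- df[[schema$outcome]]
  rows <- lapply(seq_len(nrow(schema$features)), function(i) {
    nm <- schema$features$name[i]
    kind <- schema$features$kind[i]
    v <- df[[nm]]
    if (kind == "continuous") {
      fmt <- function(z) sprintf("%.1f ± %.1f", mean(z), stats::sd(z))
      p <- tryCatch(stats::t.test(v ~ y)$p.value, error = function(e) NA_real_)
      data.frame(variable = nm, kind = kind,
                 overall = fmt(v), responders = fmt(v[y == 1]),
                 non_responders = fmt(v[y == 0]),
                 test = "welch_t", p_value = p, flag = "")
    } else {
      fmt <- function(z) sprintf("%d (%.1f%%)", sum(z == 1), 100 * mean(z == 1))
      tab <- table(factor(v), factor(y, levels = c(0, 1)))
      flag <- ""
      p <- NA_real_
      if (nrow(tab) >= 2L) {
        ht <- suppressWarnings(stats::chisq.test(tab))
        p <- ht$p.value
        if (any(ht$expected == 0)) flag <- "zero expected cell"
      } else flag <- "constant feature"
      data.frame(variable = nm, kind = kind,
                 overall = fmt(v), responders = fmt(v[y == 1]),
                 non_responders = fmt(v[y == 0]),
                 test = "chi_square", p_value = p, flag = flag)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "outcome") <- cohort_outcome_summary(y)
  class(out) <- c("uq_baseline", "data.frame")
  out
}

# Marginal outcome arithmetic: counts and percentages of each class.
cohort_outcome_summary <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1)
  c(n = n, responders = n1, non_responders = n - n1,
    responder_pct = 100 * n1 / n, non_responder_pct = 100 * (n - n1) / n)
}

#' Marginal cohort summary: class and binary-feature percentages
#'
#' @param y binary outcome vector.
#' @param ... named binary vectors (e.g. `male = ...`) to summarize as
#'   count and percentage of the whole cohort.
#' @return named numeric vector of counts and percentages.
#' @export
cohort_summary <- function(y, ...) {
  out <- cohort_outcome_summary(y)
  extra <- list(...)
  for (nm in names(extra)) {
    v <- as.numeric(extra[[nm]])
    out[paste0(nm, "_n")] <- sum(v == 1)
    out[paste0(nm, "_pct")] <- 100 * mean(v == 1)
  }
  out
}
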