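#' Define the nested cross-validation plan
#'
#' Defaults mirror the study protocol: 10 stratified outer folds (for
#' n = 218: train 196, test 22, up to rounding), two validation slices of
#' 20 patients each cut from every outer training fold (remaining train
#' 156), and stratified slicing throughout.
#'
#' @param n_outer_folds outer CV folds.
#' @param validation1_size,validation2_size per-fold validation slice sizes
#'   (`NULL` = a tenth of the outer training fold).
#' @param inner_folds inner-CV folds for hyperparameter tuning.
#' @param stratified stratify folds and slices by outcome.
#' @param seed integer seed for the whole protocol.
#' @return list of class `uq_cv_plan`.
#' @export
cv_plan <- function(n_outer_folds = 10L, validation1_size = 20L,
                    validation2_size = 20L, inner_folds = 5L,
                    stratified = TRUE, seed = 1L) {
  stopifnot(n_outer_folds >= 2L)
  structure(list(n_outer_folds = as.integer(n_outer_folds),
                 validation1_size = validation1_size,
                 validation2_size = validation2_size,
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "uq_cv_plan")
}

#' Run the full nested cross-validation protocol
#'
#' Per outer fold: fit the cascade on the training fold (which internally
#' slices validation 1 and 2, runs per-stage feature selection and
#' optional tuning, and learns the gate), then evaluate the multi-stage
#' model, Ensemble 1, Ensemble 2 and (optionally) the guideline comparator
#' on the untouched outer test fold. A leakage audit asserts
#' programmatically that every fold's test rows are disjoint from its
#' training, validation-1 and validation-2 rows and that the folds
#' partition the cohort.
#'
#' @param cohort a `uq_cohort` (or data.frame plus `schema`).
#' @param schema schema when `cohort` is a plain data.frame.
#' @param plan a [cv_plan()].
#' @param config a [cascade_config()] (validation sizes from `plan`
#'   override the config's).
#' @param guideline_map optional column map for
#'   [guideline_predict_cohort()]; `NULL` skips the comparator.
#' @return object of class `nested_cv_result`: `folds` (per-fold metrics,
#'   long format), `policies` (per-fold hyperparameters), `aggregate`
#'   (mean and sd per model and metric), `stage1_fraction` (mean and
#'   quartiles of the per-fold stage-1 fraction), `audit`, `plan`, `seed`.
#' @export
run_nested_cv <- function(cohort, schema = NULL, plan = cv_plan(),
                          config = cascade_config(), guideline_map = NULL) {
  if (inherits(cohort, "uq_cohort")) { schema <- cohort$schema; df <- cohort$data }
  else df <- as.data.frame(cohort)
  stopifnot(inherits(schema, "uq_schema"), inherits(plan, "uq_cv_plan"))
  y <- df[[schema$outcome]]
  n <- nrow(df)
  k <- plan$n_outer_folds
  fold <- if (plan$stratified) stratified_folds(y, k, plan$seed)
          else with_seed(plan$seed, sample(rep_len(seq_len(k), n)))

  fold_rows <- list(); policy_rows <- list(); audit <- list()
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    cfg <- config
    cfg$val1_size <- plan$validation1_size %||% max(2L, round(length(tr) / 10))
    cfg$val2_size <- plan$validation2_size %||% max(2L, round(length(tr) / 10))
    fit <- cascade_fit(df[tr, , drop = FALSE], schema, cfg,
                       seed = child_seed(plan$seed, f))

    test <- df[te, , drop = FALSE]
    y_te <- y[te]
    cs <- predict(fit, test)
    preds <- list(
      multi_stage = cs$final_prob,
      ensemble1 = predict(fit, test, type = "ensemble1")$mean,
      ensemble2 = predict(fit, test, type = "ensemble2")$mean)
    if (!is.null(guideline_map))
      preds$guideline <- guideline_predict_cohort(test, guideline_map)

    for (m in names(preds)) {
      met <- classification_metrics(y_te, preds[[m]])
      if (m == "guideline") met["auc"] <- NA_real_
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        fold = f, model = m, auc = met["auc"], accuracy = met["accuracy"],
        sensitivity = met["sensitivity"], specificity = met["specificity"],
        fraction_stage1 = if (m == "multi_stage")
          attr(cs, "fraction_stage1") else NA_real_,
        row.names = NULL)
    }
    pol <- fit$policy
    policy_rows[[f]] <- data.frame(
      fold = f, std_threshold = pol$std_threshold,
      midway_threshold = pol$midway_threshold,
      scaling_weight = pol$scaling_weight,
      ens1_n_models = fit$ensemble1$espec$n_models,
      ens1_fraction = fit$ensemble1$espec$sample_fraction,
      ens2_n_models = fit$ensemble2$espec$n_models,
      ens2_fraction = fit$ensemble2$espec$sample_fraction)

    # leakage audit bookkeeping: indices are relative to the full cohort
    audit[[f]] <- list(test = te, train = tr[fit$indices$train],
                       val1 = tr[fit$indices$val1], val2 = tr[fit$indices$val2])
  }

  folds <- do.call(rbind, fold_rows)
  agg <- do.call(rbind, lapply(split(folds, folds$model), function(d) {
    data.frame(model = d$model[1L],
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
               accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               sensitivity_mean = mean(d$sensitivity),
               sensitivity_sd = stats::sd(d$sensitivity),
               specificity_mean = mean(d$specificity),
               specificity_sd = stats::sd(d$specificity))
  }))
  rownames(agg) <- NULL
  fs <- folds$fraction_stage1[folds$model == "multi_stage"]
  stage1_fraction <- c(mean = mean(fs),
                       stats::quantile(fs, c(0.25, 0.5, 0.75)))

  structure(list(folds = folds, policies = do.call(rbind, policy_rows),
                 aggregate = agg, stage1_fraction = stage1_fraction,
                 audit = audit, audit_pass = audit_leakage(audit, n),
                 plan = plan, seed = plan$seed, n = n),
            class = "nested_cv_result")
}

# Programmatic leakage audit: per fold, test rows are disjoint from every
# fitting slice, the slices are mutually disjoint, and test folds
# partition the cohort.
audit_leakage <- function(audit, n) {
  all_test <- sort(unlist(lapply(audit, `[[`, "test")))
  partition_ok <- identical(all_test, seq_len(n))
  per_fold <- vapply(audit, function(a) {
    !length(intersect(a$test, c(a$train, a$val1, a$val2))) &&
      !length(intersect(a$train, a$val1)) &&
      !length(intersect(a$train, a$val2)) &&
      !length(intersect(a$val1, a$val2))
  }, TRUE)
  partition_ok && all(per_fold)
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("Nested CV (%d outer folds, n = %d)\n", x$plan$n_outer_folds, x$n))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-12s AUC %.2f (%.2f)  acc %.2f (%.2f)  sens %.2f (%.2f)  spec %.2f (%.2f)\n",
                agg$model[i], agg$auc_mean[i], agg$auc_sd[i],
                agg$accuracy_mean[i], agg$accuracy_sd[i],
                agg$sensitivity_mean[i], agg$sensitivity_sd[i],
                agg$specificity_mean[i], agg$specificity_sd[i]))
  cat(sprintf("  stage-2 acquisition needed for %.1f%% of patients (quartiles of stage-1 fraction: %.1f%% / %.1f%% / %.1f%%)\n",
              100 * (1 - x$stage1_fraction[["mean"]]),
              100 * x$stage1_fraction[["25%"]],
              100 * x$stage1_fraction[["50%"]],
              100 * x$stage1_fraction[["75%"]]))
  cat("  leakage audit:", if (x$audit_pass) "pass" else "FAIL", "\n")
  invisible(x)
}

#' Sample-size robustness simulation
#'
#' For every outer fold, the training fold is resampled *with replacement*
#' at each fraction of its size (distinct from the without-replacement
#' pseudo-bootstrap inside the ensembles), the cascade is refitted on the
#' resample, and the unchanged outer test fold is evaluated; each fraction
#' is repeated `repeats` times. Resamples whose outcome collapses to one
#' class are redrawn (up to 10 tries).
#'
#' @inheritParams run_nested_cv
#' @param fractions strictly increasing training fractions in (0, 1\].
#' @param repeats repeats per fraction.
#' @return object of class `uq_size_sim`: `runs` (per-run metrics) and
#'   `curves` (mean and sd per fraction and metric).
#' @export
sample_size_simulation <- function(cohort, schema = NULL, plan = cv_plan(),
                                   config = cascade_config(),
                                   fractions = seq(0.1, 1, by = 0.1),
                                   repeats = 3L) {
  stopifnot(all(diff(fractions) > 0), all(fractions > 0), all(fractions <= 1))
  if (inherits(cohort, "uq_cohort")) { schema <- cohort$schema; df <- cohort$data }
  else df <- as.data.frame(cohort)
  y <- df[[schema$outcome]]
  k <- plan$n_outer_folds
  fold <- stratified_folds(y, k, plan$seed)
  rows <- list()
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    for (fr in fractions) {
      for (r in seq_len(repeats)) {
        m <- max(8L, round(fr * length(tr)))
        rs_seed <- child_seed(plan$seed, f * 1000L + round(fr * 100) * 10L + r)
        for (try in 0:10) {
          idx <- with_seed(rs_seed + try,
                           sample(tr, m, replace = TRUE))
          if (length(unique(y[idx])) == 2L) break
        }
        cfg <- config
        cfg$val1_size <- max(2L, round(m / 10))
        cfg$val2_size <- max(2L, round(m / 10))
        fit <- tryCatch(
          cascade_fit(df[idx, , drop = FALSE], schema, cfg, seed = rs_seed),
          error = function(e) NULL)
        if (is.null(fit)) next
        cs <- predict(fit, df[te, , drop = FALSE])
        met <- classification_metrics(y[te], cs$final_prob)
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, fraction = fr, repeat_ = r, auc = met["auc"],
          accuracy = met["accuracy"], sensitivity = met["sensitivity"],
          specificity = met["specificity"],
          fraction_stage1 = attr(cs, "fraction_stage1"), row.names = NULL)
      }
    }
  }
  runs <- do.call(rbind, rows)
  curves <- do.call(rbind, lapply(split(runs, runs$fraction), function(d)
    data.frame(fraction = d$fraction[1L],
               auc_mean = mean(d$auc, na.rm = TRUE),
               auc_sd = stats::sd(d$auc, na.rm = TRUE),
               accuracy_mean = mean(d$accuracy, na.rm = TRUE),
               accuracy_sd = stats::sd(d$accuracy, na.rm = TRUE),
               sensitivity_mean = mean(d$sensitivity, na.rm = TRUE),
               sensitivity_sd = stats::sd(d$sensitivity, na.rm = TRUE),
               specificity_mean = mean(d$specificity, na.rm = TRUE),
               specificity_sd = stats::sd(d$specificity, na.rm = TRUE))))
  rownames(curves) <- NULL
  structure(list(runs = runs, curves = curves, plan = plan,
                 fractions = fractions, repeats = repeats),
            class = "uq_size_sim")
}

#' @export
print.uq_size_sim <- function(x, ...) {
  cat("Sample-size simulation (mean AUC by training fraction):\n")
  print(x$curves[, c("fraction", "auc_mean", "auc_sd")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a machine-readable report of a nested-CV run
#'
#' Emits `report.json` (aggregate metrics, per-fold hyperparameters,
#' stage-1 fraction distribution, seeds and plan — enough to replay the
#' run) and `folds.csv` (per-fold metric rows). An incomplete result (any
#' missing fold) is marked `incomplete = true` in the JSON.
#'
#' @param result a `nested_cv_result`.
#' @param dir output directory (created if absent).
#' @return invisibly, the path to `report.json`.
#' @export
emit_report <- function(result, dir) {
  stopifnot(inherits(result, "nested_cv_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expected <- result$plan$n_outer_folds
  got <- length(unique(result$folds$fold))
  report <- list(
    incomplete = got < expected,
    n = result$n,
    seed = result$seed,
    plan = unclass(result$plan),
    aggregate = result$aggregate,
    stage1_fraction = as.list(result$stage1_fraction),
    policies = result$policies,
    audit_pass = result$audit_pass)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  utils::write.csv(result$folds, file.path(dir, "folds.csv"),
                   row.names = FALSE)
  invisible(path)
}
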