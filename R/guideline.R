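#' Default CRT recommendation rule table
#'
#' Encodes the 2012 ACCF/AHA/HRS-style recommendation classes used as the
#' rule-based comparator: Class I for LVEF <= 35%, LBBB and QRSd >= 150 ms
#' in NYHA II–IV; Class IIa for the same substrate with 120 <= QRSd < 150
#' ms, or for non-LBBB with QRSd >= 150 ms in NYHA III–IV. A terminal
#' "none" row makes the table total. The table is plain data and may be
#' edited or replaced from a YAML file — sinus-rhythm and medical-therapy
#' criteria are not represented because they are not among the modelled
#' variables.
#'
#' @return data.frame with columns `class`, `lvef_max`, `lbbb`
#'   (TRUE/FALSE/NA = any), `qrs_min`, `qrs_max` (interval
#'   `[qrs_min, qrs_max)`), `nyha` (comma-separated classes). First
#'   matching row wins.
#' @export
default_guideline_rules <- function() {
  data.frame(
    class = c("I", "IIa", "IIa", "none"),
    lvef_max = c(35, 35, 35, Inf),
    lbbb = c(TRUE, TRUE, FALSE, NA),
    qrs_min = c(150, 120, 150, -Inf),
    qrs_max = c(Inf, 150, Inf, Inf),
    nyha = c("II,III,IV", "II,III,IV", "III,IV", "I,II,III,IV"),
    stringsAsFactors = FALSE)
}

#' Read a guideline rule table from YAML
#' @param path YAML file with a `rules` list of rows matching
#'   [default_guideline_rules()]'s columns.
#' @return rule-table data.frame.
#' @export
read_guideline_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw$rules, function(r) data.frame(
    class = r$class,
    lvef_max = as.numeric(r$lvef_max %||% Inf),
    lbbb = if (is.null(r$lbbb)) NA else as.logical(r$lbbb),
    qrs_min = as.numeric(r$qrs_min %||% -Inf),
    qrs_max = as.numeric(r$qrs_max %||% Inf),
    nyha = r$nyha %||% "I,II,III,IV",
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

normalize_nyha <- function(v) {
  if (is.numeric(v)) c("I", "II", "III", "IV")[v]
  else toupper(as.character(v))
}

#' Classify patients by the guideline rule table
#'
#' First matching row wins; a patient is predicted a responder iff the
#' matched class is I or IIa. Missing fields raise an error — there is no
#' silent default class.
#'
#' @param patients data.frame with columns `LVEF` (percent), `LBBB`
#'   (logical/0-1), `QRSd` (ms), `NYHA` (I–IV or 1–4).
#' @param rules rule table (default [default_guideline_rules()]).
#' @return data.frame with `class` and `predicted_responder`.
#' @export
classify_guideline <- function(patients, rules = default_guideline_rules()) {
  req <- c("LVEF", "LBBB", "QRSd", "NYHA")
  absent <- setdiff(req, names(patients))
  if (length(absent))
    stop("missing guideline field(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (any(is.na(patients[, req])))
    stop("guideline fields contain missing values", call. = FALSE)
  if (any(patients$LVEF <= 0 | patients$LVEF >= 100) || any(patients$QRSd <= 0))
    stop("LVEF must lie in (0, 100) and QRSd must be positive", call. = FALSE)
  nyha <- normalize_nyha(patients$NYHA)
  lbbb <- as.logical(patients$LBBB)
  cls <- character(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    for (r in seq_len(nrow(rules))) {
      nyha_ok <- nyha[i] %in% strsplit(rules$nyha[r], ",")[[1]]
      lbbb_ok <- is.na(rules$lbbb[r]) || lbbb[i] == rules$lbbb[r]
      if (patients$LVEF[i] <= rules$lvef_max[r] && lbbb_ok &&
          patients$QRSd[i] >= rules$qrs_min[r] &&
          patients$QRSd[i] < rules$qrs_max[r] && nyha_ok) {
        cls[i] <- rules$class[r]
        break
      }
    }
    if (cls[i] == "") cls[i] <- "none"
  }
  data.frame(class = cls, predicted_responder = cls %in% c("I", "IIa"))
}

#' Guideline predictions for a modelling cohort
#'
#' Maps cohort columns onto the guideline fields and returns a 0/1
#' prediction vector suitable for the evaluation functions.
#'
#' @param data cohort data.frame.
#' @param map named list giving the cohort column for each of `LVEF`,
#'   `LBBB`, `QRSd`, `NYHA`.
#' @param rules rule table.
#' @return integer vector of predicted responses (1 = responder).
#' @export
guideline_predict_cohort <- function(data,
                                     map = list(LVEF = "LVEF", LBBB = "LBBB",
                                                QRSd = "QRSd", NYHA = "NYHA"),
                                     rules = default_guideline_rules()) {
  if (nrow(data) == 0L) return(integer(0))
  absent <- setdiff(unlist(map), names(data))
  if (length(absent))
    stop("unmapped guideline column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  patients <- data.frame(LVEF = data[[map$LVEF]], LBBB = data[[map$LBBB]],
                         QRSd = data[[map$QRSd]], NYHA = data[[map$NYHA]])
  as.integer(classify_guideline(patients, rules)$predicted_responder)
}

#' Compare a probabilistic model against the guideline comparator
#'
#' McNemar tests on sensitivity (positives) and specificity (negatives);
#' the AUC comparison is reported as not applicable because the guideline
#' rule emits a binary label, not a score.
#'
#' @param labels binary outcome vector.
#' @param model_probs model probabilities.
#' @param guideline_preds 0/1 guideline predictions.
#' @param cutoff model classification cutoff.
#' @return list with `sensitivity`, `specificity` ([mcnemar_test()]
#'   results) and `auc = NA`.
#' @export
guideline_comparison <- function(labels, model_probs, guideline_preds,
                                 cutoff = 0.5) {
  labels <- as.numeric(labels)
  mod <- as.numeric(model_probs >= cutoff)
  gl <- as.numeric(guideline_preds)
  pos <- labels == 1; neg <- !pos
  list(auc = NA,
       sensitivity = mcnemar_test(mod[pos] == 1, gl[pos] == 1),
       specificity = mcnemar_test(mod[neg] == 0, gl[neg] == 0))
}
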