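#' Define a two-stage feature schema
#'
#' A schema assigns every feature a value kind (`continuous`, `binary` or
#' `categorical`) and an acquisition stage: stage 1 for cheap features
#' (e.g. baseline clinical variables and ECG markers) and stage 2 for
#' expensive ones (e.g. SPECT-derived perfusion and dyssynchrony measures).
#' The outcome column is named separately and is never listed among the
#' features.
#'
#' @param features data.frame with columns `name`, `kind`, `stage`, or a
#'   named list `name = list(kind =, stage =)`.
#' @param outcome name of the binary outcome column (1 = responder).
#' @return An object of class `uq_schema`.
#' @examples
#' feature_schema(
#'   data.frame(name = c("age", "qrsd", "lvef"),
#'              kind = c("continuous", "continuous", "continuous"),
#'              stage = c(1, 1, 2)),
#'   outcome = "response")
#' @export
feature_schema <- function(features, outcome) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- data.frame(
      name = names(features),
      kind = vapply(features, function(f) f$kind, ""),
      stage = vapply(features, function(f) as.numeric(f$stage), 0),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(features),
            all(c("name", "kind", "stage") %in% names(features)))
  features$name <- as.character(features$name)
  features$kind <- as.character(features$kind)
  features$stage <- as.integer(features$stage)
  if (anyDuplicated(features$name))
    stop("duplicate feature names in schema", call. = FALSE)
  bad <- setdiff(features$kind, c("continuous", "binary", "categorical"))
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!all(features$stage %in% c(1L, 2L)))
    stop("feature stages must be 1 or 2", call. = FALSE)
  if (!is.character(outcome) || length(outcome) != 1L || !nzchar(outcome))
    stop("`outcome` must be a single column name", call. = FALSE)
  if (outcome %in% features$name)
    stop("outcome column must not be listed among the features", call. = FALSE)
  features <- features[, c("name", "kind", "stage")]
  rownames(features) <- NULL
  structure(list(features = features, outcome = outcome),
            class = "uq_schema")
}

#' @export
print.uq_schema <- function(x, ...) {
  cat("Two-stage feature schema\n")
  cat("  outcome:", x$outcome, "\n")
  cat("  stage 1:", sum(x$features$stage == 1L), "features;",
      "stage 2:", sum(x$features$stage == 2L), "features\n")
  invisible(x)
}

#' Read a feature schema from a YAML or JSON file
#'
#' The file maps each feature name to `{kind, stage}` under a `features`
#' key and names the outcome column under an `outcome` key.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return An `uq_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  if (is.null(raw$features) || is.null(raw$outcome))
    stop("schema file must contain `features` and `outcome`", call. = FALSE)
  feature_schema(raw$features, raw$outcome)
}

#' Write a feature schema to YAML
#' @param schema an `uq_schema`.
#' @param path output file path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "uq_schema"))
  feats <- lapply(seq_len(nrow(schema$features)), function(i)
    list(kind = schema$features$kind[i], stage = schema$features$stage[i]))
  names(feats) <- schema$features$name
  yaml::write_yaml(list(outcome = schema$outcome, features = feats), path)
  invisible(path)
}

#' Feature names belonging to given stage(s)
#' @param schema an `uq_schema`.
#' @param stage 1, 2, or `c(1, 2)`.
#' @return character vector of feature names, in schema order.
#' @export
stage_features <- function(schema, stage) {
  schema$features$name[schema$features$stage %in% stage]
}

# Check that a schema supports cascade modelling: both stages populated.
assert_cascade_schema <- function(schema) {
  if (sum(schema$features$stage == 1L) < 1L ||
      sum(schema$features$stage == 2L) < 1L)
    stop("cascade modelling needs at least one stage-1 and one stage-2 feature",
         call. = FALSE)
  invisible(schema)
}
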