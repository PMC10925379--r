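#' Serialize a fitted ensemble to JSON
#'
#' Stores member intercepts and slopes, preprocessing parameters, and both
#' specs — everything needed for inference — in plain JSON.
#'
#' @param model a `uq_ensemble`.
#' @param path output file.
#' @export
write_ensemble_json <- function(model, path) {
  stopifnot(inherits(model, "uq_ensemble"))
  obj <- list(
    type = "uq_ensemble",
    features = model$features,
    outcome = model$outcome,
    n_train = model$n_train,
    espec = unclass(model$espec),
    bspec = unclass(model$bspec),
    preprocess = list(center = as.list(model$preprocess$center),
                      scale = as.list(model$preprocess$scale),
                      features = model$preprocess$features,
                      dropped = model$preprocess$dropped,
                      spatial_sign = model$preprocess$spatial_sign),
    members = lapply(model$members, function(m)
      list(intercept = m$intercept, beta = as.list(m$beta))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted ensemble back from JSON
#' @param path file written by [write_ensemble_json()].
#' @return a `uq_ensemble` usable for prediction.
#' @export
read_ensemble_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(obj$type, "uq_ensemble"))
  pre <- structure(list(center = unlist(obj$preprocess$center),
                        scale = unlist(obj$preprocess$scale),
                        features = unlist(obj$preprocess$features),
                        dropped = unlist(obj$preprocess$dropped) %||% character(0),
                        spatial_sign = isTRUE(obj$preprocess$spatial_sign)),
                   class = "uq_preproc")
  bspec <- base_learner_spec(obj$bspec$alpha, obj$bspec$lambda,
                             obj$bspec$thresh, obj$bspec$maxit)
  espec <- ensemble_spec(obj$espec$n_models, obj$espec$sample_fraction,
                         obj$espec$seed)
  members <- lapply(obj$members, function(m)
    structure(list(intercept = m$intercept, beta = unlist(m$beta),
                   spec = bspec, converged = TRUE),
              class = "uq_base_fit"))
  structure(list(members = members, preprocess = pre,
                 features = unlist(obj$features), outcome = obj$outcome,
                 espec = espec, bspec = bspec, n_train = obj$n_train),
            class = "uq_ensemble")
}

#' Serialize a gate policy to JSON
#' @param policy a `uq_gate_policy`.
#' @param path output file.
#' @export
write_policy_json <- function(policy, path) {
  stopifnot(inherits(policy, "uq_gate_policy"))
  jsonlite::write_json(unclass(policy), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gate policy from JSON
#' @param path file written by [write_policy_json()].
#' @return a `uq_gate_policy`.
#' @export
read_policy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gate_policy(obj$std_threshold, obj$midway_threshold,
              obj$scaling_weight %||% NA)
}
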