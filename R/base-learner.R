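#' Specify an elastic-net logistic base learner
#'
#' The base learner minimizes the mean negative Bernoulli log-likelihood
#' plus `lambda * (alpha * L1 + (1 - alpha)/2 * L2)` on the slope
#' coefficients (intercept unpenalized), i.e. the standard elastic-net
#' objective. `alpha = 0` is ridge, `alpha = 1` is lasso.
#'
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda regularization strength, >= 0.
#' @param thresh optimizer convergence tolerance.
#' @param maxit maximum optimizer iterations.
#' @return list of class `uq_base_spec`.
#' @export
base_learner_spec <- function(alpha = 0.5, lambda = 0.01,
                              thresh = 1e-9, maxit = 1e5) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0, thresh > 0, maxit >= 1)
  structure(list(alpha = alpha, lambda = lambda, thresh = thresh,
                 maxit = maxit), class = "uq_base_spec")
}

#' Fit one elastic-net logistic base learner
#'
#' Thin wrapper over [glmnet::glmnet()] at a single fixed `lambda`, on
#' already-standardized features (`standardize = FALSE`). The fitted object
#' stores only the intercept and slope vector, making it cheap to carry in
#' an ensemble and trivially serializable.
#'
#' @param x numeric matrix of (preprocessed) features.
#' @param y binary outcome vector (0/1), both classes present.
#' @param spec a [base_learner_spec()].
#' @return list of class `uq_base_fit` with `intercept`, `beta` (named),
#'   `spec`, `converged`.
#' @export
fit_base <- function(x, y, spec = base_learner_spec()) {
  stopifnot(inherits(spec, "uq_base_spec"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot fit base learner", call. = FALSE)
  # glmnet needs >= 2 columns; pad single-feature fits with an all-zero
  # dummy whose coefficient is identically zero and is dropped afterwards
  pad <- ncol(x) == 1L
  if (pad) x <- cbind(x, `..pad..` = 0)
  fit <- suppressWarnings(glmnet::glmnet(
    x, y, family = "binomial", alpha = spec$alpha,
    lambda = spec$lambda, standardize = FALSE,
    thresh = spec$thresh, maxit = spec$maxit))
  converged <- is.null(fit$jerr) || all(fit$jerr == 0)
  if (!converged)
    warning("base learner fit did not fully converge (glmnet jerr = ",
            paste(fit$jerr, collapse = ","), ")", call. = FALSE)
  cf <- as.matrix(stats::coef(fit, s = spec$lambda))[, 1L]
  if (pad) cf <- cf[names(cf) != "..pad.."]
  structure(list(intercept = unname(cf[1L]), beta = cf[-1L], spec = spec,
                 converged = converged),
            class = "uq_base_fit")
}

#' Predict response probabilities from a fitted base learner
#' @param object a `uq_base_fit`.
#' @param newx matrix with the training feature columns.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.uq_base_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  absent <- setdiff(names(object$beta), colnames(newx))
  if (length(absent))
    stop("feature(s) missing at prediction: ", paste(absent, collapse = ", "),
         call. = FALSE)
  eta <- drop(newx[, names(object$beta), drop = FALSE] %*% object$beta) +
    object$intercept
  sigmoid(eta)
}
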