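# Mean-field Gaussian variational machinery (Bayes by Backprop).
#
# Every stochastic weight tensor carries a fully factorised Gaussian
# posterior q(w) = N(mean, softplus(rho)^2), sampled by reparameterisation.

#' Construct a mean-field Gaussian posterior over a weight tensor
#'
#' @param mean numeric vector/matrix of variational means.
#' @param sd initial standard deviation(s); stored internally as the
#'   unconstrained `rho` with `sd = softplus(rho)`. Default 0.05, small
#'   relative to the 0.374 prior scale so training starts near the
#'   deterministic model.
#' @return an object of class `mean_field_posterior` with fields `mean`
#'   and `rho` of identical shape.
#' @export
mean_field_posterior <- function(mean, sd = 0.05) {
  stopifnot(all(sd > 0))
  rho <- mean * 0 + softplus_inv(sd)
  structure(list(mean = mean, rho = rho), class = "mean_field_posterior")
}

#' Posterior standard deviations
#' @param posterior a `mean_field_posterior`.
#' @return array of positive sds, same shape as the mean.
#' @export
posterior_sd <- function(posterior) softplus(posterior$rho)

#' Reparameterised weight draw
#'
#' Draws `w = mean + softplus(rho) * eps`, `eps ~ N(0, I)`, using the
#' current R random stream. Returns the draw together with the noise so
#' gradients can be routed back to `mean` and `rho`.
#'
#' @param posterior a `mean_field_posterior`.
#' @return list with `w` (the sampled weights) and `eps` (the standard
#'   normal noise used).
#' @export
sample_weights <- function(posterior) {
  eps <- array(stats::rnorm(length(posterior$mean)), dim = dim(posterior$mean) %||% length(posterior$mean))
  if (is.null(dim(posterior$mean))) eps <- as.vector(eps)
  w <- posterior$mean + posterior_sd(posterior) * eps
  list(w = w, eps = eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prior over stochastic weights
#'
#' Zero-mean isotropic Gaussian prior; the default scale 0.374 is the
#' package default for all stochastic weight groups.
#' @param mean prior mean (default 0).
#' @param sd prior standard deviation (default 0.374).
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(mean = 0, sd = 0.374) {
  if (sd <= 0) stop("prior sd must be positive")
  structure(list(mean = mean, sd = sd), class = "prior_spec")
}

#' KL divergence from a mean-field posterior to its Gaussian prior
#'
#' Closed form, summed over all weights:
#' `sum( log(sd0/sd) + (sd^2 + (mu - mu0)^2) / (2 sd0^2) - 1/2 )`.
#'
#' @param posterior a `mean_field_posterior`.
#' @param prior a `prior_spec`.
#' @return non-negative scalar (nats).
#' @export
kl_to_prior <- function(posterior, prior = prior_spec()) {
  if (prior$sd <= 0) stop("prior sd must be positive")
  sd <- posterior_sd(posterior)
  mu <- posterior$mean
  sum(log(prior$sd / sd) + (sd^2 + (mu - prior$mean)^2) / (2 * prior$sd^2) - 0.5)
}

# Gradients of kl_to_prior w.r.t. mean and rho (same shapes).
kl_to_prior_grad <- function(posterior, prior = prior_spec()) {
  sd <- posterior_sd(posterior)
  dmean <- (posterior$mean - prior$mean) / prior$sd^2
  dsd <- -1 / sd + sd / prior$sd^2
  drho <- dsd * sigmoid(posterior$rho)    # d softplus / d rho
  list(mean = dmean, rho = drho)
}

#' Blundell minibatch KL weight
#'
#' Geometric schedule `2^(M-i) / (2^M - 1)` over the `M` minibatches of an
#' epoch: early batches absorb most of the complexity cost. The weights of
#' one epoch sum to one.
#'
#' @param i batch index, 1-based.
#' @param m number of batches per epoch.
#' @return a fraction in (0, 1].
#' @export
minibatch_kl_weight <- function(i, m) {
  if (i < 1 || i > m) stop("batch index out of range")
  # 2^(M-i)/(2^M - 1) rewritten so it cannot overflow for large M
  2^(-i) / (1 - 2^(-m))
}

#' Bayesian linear classifier forward pass
#'
#' Affine map of a pooled feature vector using one sampled (or point)
#' weight draw; the logistic transfer is applied downstream.
#'
#' @param pooled numeric vector, or matrix with one row per example.
#' @param weights list with `w` (length `d`) and `b` (scalar), e.g. one
#'   draw from the classifier posterior.
#' @return logit(s).
#' @export
bayesian_linear_forward <- function(pooled, weights) {
  if (is.matrix(pooled)) {
    if (ncol(pooled) != length(weights$w)) stop("pooled dimension mismatch")
    drop(pooled %*% weights$w) + weights$b
  } else {
    if (length(pooled) != length(weights$w)) stop("pooled dimension mismatch")
    sum(pooled * weights$w) + weights$b
  }
}
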