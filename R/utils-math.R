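# Small numerical primitives shared across the encoder, variational and GP code.

#' Numerically stable logistic function
#' @param x numeric vector or matrix of logits.
#' @return values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Softplus and its inverse
#'
#' `softplus` maps unconstrained variational scale parameters to positive
#' standard deviations; `softplus_inv` is used to initialise them.
#' @param x numeric vector.
#' @return numeric vector, same shape.
#' @export
softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' @rdname softplus
#' @export
softplus_inv <- function(x) {
  stopifnot(all(x > 0))
  x + log(-expm1(-x))
}

# log(1 + exp(x)), elementwise, stable
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Gauss-Hermite nodes/weights (physicists' convention), cached per order.
.gh_cache <- new.env(parent = emptyenv())
gauss_hermite <- function(order = 20L) {
  key <- as.character(order)
  if (is.null(.gh_cache[[key]])) {
    stopifnot(order >= 1L)
    .gh_cache[[key]] <- pracma::gaussHermite(order)
  }
  .gh_cache[[key]]
}

#' Expected Bernoulli log-likelihood and logistic mean under a Gaussian latent
#'
#' Computes `E[log p(y|f)]` and `E[sigmoid(f)]` for `f ~ N(mean, var)` by
#' Gauss-Hermite quadrature. Both are the workhorses of the GP classification
#' head: the first inside the training objective, the second when turning a
#' latent marginal into a predictive probability.
#'
#' @param mean,var numeric vectors (recycled to common length); `var >= 0`.
#' @param y binary labels in `{0,1}` (for the log-likelihood only).
#' @param order quadrature order.
#' @return `gauss_expected_sigmoid`: probabilities in (0,1).
#' @export
gauss_expected_sigmoid <- function(mean, var, order = 20L) {
  if (any(var < 0)) stop("latent variance must be non-negative")
  gh <- gauss_hermite(order)
  n <- max(length(mean), length(var))
  mean <- rep_len(mean, n); var <- rep_len(var, n)
  f <- outer(sqrt(2 * var), gh$x) + mean   # n x order
  drop(sigmoid(f) %*% gh$w) / sqrt(pi)
}

# E[y f - log(1+e^f)] under N(mean, var), plus derivatives w.r.t. mean and var.
# Returns list(value, dmean, dvar); all length-n vectors.
gauss_expected_bernoulli_ll <- function(y, mean, var, order = 20L) {
  if (any(var < 0)) stop("latent variance must be non-negative")
  gh <- gauss_hermite(order)
  n <- length(mean)
  s <- sqrt(2 * pmax(var, 0))
  f <- outer(s, gh$x) + mean               # n x order
  ll <- y * f - log1pexp(f)
  dll <- y - sigmoid(f)                     # d ll / d f
  w <- gh$w / sqrt(pi)
  value <- drop(ll %*% w)
  dmean <- drop(dll %*% w)
  # d f / d var = x_k / (2 * s); guard the deterministic limit s -> 0
  safe_s <- pmax(s, 1e-8)
  dvar <- drop((dll * outer(1 / safe_s, gh$x)) %*% w)
  list(value = value, dmean = dmean, dvar = dvar)
}

#' Closed-form KL divergence between two univariate Gaussians
#'
#' `KL( N(mu_f, sd_f^2) || N(mu_t, sd_t^2) )` in nats.
#' @param mu_f,sd_f mean and standard deviation of the first Gaussian.
#' @param mu_t,sd_t mean and standard deviation of the second Gaussian.
#' @return non-negative scalar.
#' @export
gaussian_kl <- function(mu_f, sd_f, mu_t, sd_t) {
  stopifnot(sd_f > 0, sd_t > 0)
  log(sd_t / sd_f) + (sd_f^2 + (mu_f - mu_t)^2) / (2 * sd_t^2) - 0.5
}

# Deterministic child seed: combine a base seed and a stream label into a
# 31-bit integer, so every stochastic stage draws from its own stream.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
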