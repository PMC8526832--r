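# GP classification heads: latent marginals, the Bernoulli ELBO, the
# logistic-Gaussian integral, and analytic gradients (including the
# Cholesky adjoint) against oracles.

test_that("a prior-state head predicts latent mean 0 and variance k(x,x)", {
  set.seed(10)
  head <- gp_head_init("svgp", dim = 3, n_inducing = 8)
  x <- matrix(runif(15, -0.8, 0.8), 5, 3)
  lat <- predictive_latent(x, head)
  expect_equal(lat$mean, rep(0, 5))
  expect_equal(lat$var, rep(exp(head$params$log_os), 5), tolerance = 1e-4)
  expect_true(all(lat$var > 0))
  expect_equal(gp_head_kl(head), 0, tolerance = 1e-12)
})

test_that("querying at an inducing point with a point-mass posterior recovers it", {
  set.seed(11)
  head <- gp_head_init("svgp", dim = 2, n_inducing = 6)
  head$params$c_log_diag[] <- -25          # collapse the variational cov
  head$params$vm <- rnorm(6, 0, 0.5)
  z <- head$params$z
  lat <- predictive_latent(z, head)
  kp <- kernel_params(exp(head$params$log_ls), exp(head$params$log_os), 1)
  l <- bgpseq:::chol_lower(rbf_kernel(z, z, kp))
  expect_equal(lat$mean, drop(l %*% head$params$vm), tolerance = 1e-4)
  expect_lt(max(lat$var), 1e-4)            # -> 0 as jitter -> 0
})

test_that("batched latent evaluation equals one-at-a-time evaluation", {
  set.seed(12)
  for (type in c("svgp", "kiss")) {
    head <- gp_head_init(type, dim = 2, n_inducing = 7, grid_size = 12)
    head$params$vm <- head$params$vm + rnorm(length(head$params$vm), 0, 0.3)
    x <- matrix(runif(100, -0.9, 0.9), 50, 2)
    lat <- predictive_latent(x, head)
    for (i in c(1, 17, 50)) {
      one <- predictive_latent(x[i, , drop = FALSE], head)
      expect_equal(lat$mean[i], one$mean, tolerance = 1e-10)
      expect_equal(lat$var[i], one$var, tolerance = 1e-10)
    }
  }
})

test_that("latent-to-probability matches Monte Carlo and its limits", {
  expect_equal(latent_to_probability(0, 0), 0.5)
  expect_equal(latent_to_probability(3, 1e8), 0.5, tolerance = 1e-3)
  set.seed(13)
  z <- rnorm(5e5)                       # antithetic million-draw estimate
  mc <- mean((sigmoid(1 + z) + sigmoid(1 - z)) / 2)
  expect_equal(latent_to_probability(1, 1), mc, tolerance = 1e-4)
  expect_error(latent_to_probability(0, -1), "non-negative")
  # monotone in the mean at fixed variance
  p <- latent_to_probability(seq(-3, 3, by = 0.5), 0.7)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("expected Bernoulli log-likelihood quadrature matches Monte Carlo", {
  set.seed(14)
  mu <- 0.6; v <- 1.3
  e <- bgpseq:::gauss_expected_bernoulli_ll(1, mu, v, order = 20)
  z <- rnorm(5e5) * sqrt(v)             # antithetic million-draw estimate
  ll <- function(f) 1 * f - log1p(exp(f))
  expect_equal(e$value, mean((ll(mu + z) + ll(mu - z)) / 2), tolerance = 1e-3)
  quad <- stats::integrate(function(f) ll(f) * dnorm(f, mu, sqrt(v)),
                           -20, 20, rel.tol = 1e-10)$value
  expect_equal(e$value, quad, tolerance = 1e-6)
  # latent point-mass at zero gives log(1/2) per point
  e0 <- bgpseq:::gauss_expected_bernoulli_ll(c(0, 1), c(0, 0), c(0, 0))
  expect_equal(e0$value, rep(log(0.5), 2), tolerance = 1e-10)
})

test_that("classification ELBO decomposes into quadrature data term minus whitened KL", {
  set.seed(15)
  head <- gp_head_init("svgp", dim = 2, n_inducing = 5)
  head$params$vm <- rnorm(5, 0, 0.4)
  head$params$c_off[lower.tri(head$params$c_off)] <- rnorm(10, 0, 0.1)
  head$params$c_log_diag <- rnorm(5, 0, 0.2)
  x <- matrix(runif(12, -0.7, 0.7), 6, 2)
  y <- c(1, 0, 1, 1, 0, 0)
  elbo <- svgp_classification_elbo(x, y, head, n_total = 60)
  lat <- predictive_latent(x, head)
  e <- bgpseq:::gauss_expected_bernoulli_ll(y, lat$mean, lat$var)
  cmat <- bgpseq:::head_cfactor(head$params$c_off, head$params$c_log_diag)
  kl_oracle <- dense_whitened_kl(head$params$vm, tcrossprod(cmat))
  expect_equal(elbo, 10 * sum(e$value) - kl_oracle, tolerance = 1e-8)
  expect_equal(gp_head_kl(head), kl_oracle, tolerance = 1e-8)
  expect_error(svgp_classification_elbo(x, y, head, order = 0), "order")
})

test_that("KISS head ELBO approaches a sparse head with grid inducing points", {
  set.seed(16)
  x <- matrix(runif(30, -0.9, 0.9), 30, 1)
  y <- rbinom(30, 1, 0.4)
  gaps <- vapply(c(8L, 32L, 128L), function(g) {
    kiss <- gp_head_init("kiss", dim = 1, grid_size = g)
    set.seed(2)
    kiss$params$vm[] <- rnorm(g, 0, 0.5)
    kiss$params$c_log_diag[] <- rnorm(g, 0, 0.2)
    svgp <- gp_head_init("svgp", dim = 1, n_inducing = g)
    svgp$params$z <- matrix(kiss$const$grid, ncol = 1)
    svgp$params$log_ls <- kiss$params$log_ls
    svgp$params$log_os <- kiss$params$log_os
    svgp$params$vm <- as.vector(kiss$params$vm)
    svgp$params$c_log_diag <- as.vector(kiss$params$c_log_diag)
    abs(svgp_classification_elbo(x, y, kiss, 30) -
          svgp_classification_elbo(x, y, svgp, 30))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("Cholesky adjoint and head gradients agree with finite differences", {
  set.seed(17)
  k0 <- crossprod(matrix(rnorm(25), 5)) + diag(0.5, 5)
  l0 <- bgpseq:::chol_lower(k0, 0)
  lbar <- matrix(rnorm(25), 5); lbar[upper.tri(lbar)] <- 0
  dk <- bgpseq:::chol_adjoint(l0, lbar)
  f <- function(kvec) {
    k <- matrix(kvec, 5); k <- (k + t(k)) / 2
    sum(bgpseq:::chol_lower(k, 0) * lbar)
  }
  fd <- matrix(fd_gradient(f, as.vector(k0)), 5)
  expect_equal(dk, (fd + t(fd)) / 2, tolerance = 1e-5)
})

test_that("full head backward passes a finite-difference check", {
  set.seed(18)
  for (type in c("svgp", "kiss")) {
    head <- gp_head_init(type, dim = 2, n_inducing = 5, grid_size = 8)
    head$params$vm <- head$params$vm + rnorm(length(head$params$vm), 0, 0.3)
    head$params$c_log_diag[] <- head$params$c_log_diag + 0.1
    x <- matrix(runif(8, -0.7, 0.7), 4, 2)
    y <- c(1, 0, 0, 1)
    loss_of <- function(params, xx = x) {
      h2 <- head; h2$params <- params
      -svgp_classification_elbo(xx, y, h2, n_total = 12)
    }
    lat <- predictive_latent(x, head)
    e <- bgpseq:::gauss_expected_bernoulli_ll(y, lat$mean, lat$var)
    hb <- bgpseq:::gp_head_backward(head, lat$cache, -3 * e$dmean, -3 * e$dvar,
                                    klw = 1)
    set.seed(99)
    expect_lt(fd_check_tree(loss_of, head$params, hb$grads, per_leaf = 4L), 1e-4)
    # gradient w.r.t. the pooled inputs
    fd_x <- matrix(fd_gradient(function(v) loss_of(head$params, matrix(v, 4, 2)),
                               as.vector(x)), 4, 2)
    expect_equal(hb$dx, fd_x, tolerance = 1e-4)
  }
})
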