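# Gaussian-process classification heads over the pooled encoder features.
#
# Two flavours share one whitened variational parameterisation with prior
# N(0, I) over the inducing values:
#   * "svgp": free inducing point locations (default 40) with a full RBF
#     kernel over the pooled space;
#   * "kiss": structured kernel interpolation with one fixed 1-D grid per
#     pooled dimension and an additive kernel across dimensions (a tensor
#     grid is infeasible beyond a couple of dimensions).
# The Bernoulli expected log-likelihood is computed by Gauss-Hermite
# quadrature (order 20); all gradients, including those flowing back into
# the encoder features, are analytic.

GP_JITTER <- 1e-6
GH_ORDER <- 20L
VAR_FLOOR <- 1e-10

#' Initialise a GP classification head
#'
#' @param type `"svgp"` (free inducing points) or `"kiss"` (additive
#'   per-dimension grids).
#' @param dim pooled feature dimensionality.
#' @param n_inducing number of free inducing points (svgp; default 40).
#' @param grid_size grid points per dimension (kiss).
#' @param grid_range grid extent; the default covers the (-1, 1) range of
#'   the tanh pooled features with margin.
#' @param lengthscale,outputscale initial kernel hyperparameters.
#' @return a `gp_head`: list with `const` (structure) and `params`
#'   (trainable tree).
#' @export
gp_head_init <- function(type = c("svgp", "kiss"), dim,
                         n_inducing = 40L, grid_size = 64L,
                         grid_range = c(-1.1, 1.1),
                         lengthscale = 1, outputscale = 1) {
  type <- match.arg(type)
  if (type == "svgp") {
    m <- as.integer(n_inducing)
    params <- list(z = matrix(stats::runif(m * dim, -0.8, 0.8), m, dim),
                   log_ls = log(lengthscale), log_os = log(outputscale),
                   vm = numeric(m),
                   c_off = matrix(0, m, m),
                   c_log_diag = numeric(m))
    const <- list(type = type, dim = dim, m = m)
  } else {
    g <- as.integer(grid_size)
    params <- list(log_ls = rep(log(lengthscale), dim),
                   log_os = rep(log(outputscale / dim), dim),
                   vm = matrix(0, g, dim),
                   c_off = array(0, c(g, g, dim)),
                   c_log_diag = matrix(0, g, dim))
    const <- list(type = type, dim = dim, g = g,
                  grid = kiss_grid(grid_range[1], grid_range[2], g))
  }
  structure(list(const = const, params = params), class = "gp_head")
}

# Assemble the lower-triangular covariance factor from its free storage.
head_cfactor <- function(c_off, c_log_diag) {
  cmat <- c_off
  cmat[upper.tri(cmat, diag = TRUE)] <- 0
  diag(cmat) <- exp(c_log_diag)
  cmat
}

# Split a full dC back into the free storage gradients.
cfactor_grads <- function(dc, c_log_diag) {
  doff <- dc
  doff[upper.tri(doff, diag = TRUE)] <- 0
  list(c_off = doff, c_log_diag = diag(dc) * exp(c_log_diag))
}

#' KL divergence of the whitened variational distribution to N(0, I)
#' @param head a `gp_head`.
#' @return non-negative scalar.
#' @export
gp_head_kl <- function(head) {
  p <- head$params
  if (head$const$type == "svgp") {
    cmat <- head_cfactor(p$c_off, p$c_log_diag)
    0.5 * (sum(cmat^2) + sum(p$vm^2) - head$const$m) - sum(p$c_log_diag)
  } else {
    total <- 0
    for (d in seq_len(head$const$dim)) {
      cmat <- head_cfactor(p$c_off[, , d], p$c_log_diag[, d])
      total <- total + 0.5 * (sum(cmat^2) + sum(p$vm[, d]^2) - head$const$g) -
        sum(p$c_log_diag[, d])
    }
    total
  }
}

#' Latent predictive marginals of a GP head
#'
#' Per-point latent mean and variance of the sparse-GP conditional under
#' the whitened variational distribution.
#'
#' @param pooled B x dim matrix of pooled features.
#' @param head a `gp_head`.
#' @return list with numeric vectors `mean` and `var` (strictly positive
#'   up to jitter) plus a backward `cache`.
#' @export
predictive_latent <- function(pooled, head) {
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = 1)
  if (ncol(pooled) != head$const$dim) stop("pooled dimension mismatch")
  p <- head$params
  if (head$const$type == "svgp") {
    ls <- exp(p$log_ls); os <- exp(p$log_os)
    kp <- kernel_params(ls, os, 1)
    kuu <- rbf_kernel(p$z, p$z, kp)
    l <- chol_lower(kuu, GP_JITTER)
    kuf <- rbf_kernel(p$z, pooled, kp)
    a <- forwardsolve(l, kuf)                   # M x B
    cmat <- head_cfactor(p$c_off, p$c_log_diag)
    cta <- crossprod(cmat, a)                   # C^T A
    mu <- drop(crossprod(a, p$vm))
    var <- pmax(os - colSums(a^2) + colSums(cta^2), VAR_FLOOR)
    cache <- list(type = "svgp", x = pooled, kuu = kuu, l = l, kuf = kuf,
                  a = a, cmat = cmat, cta = cta, kp = kp)
    list(mean = mu, var = var, cache = cache)
  } else {
    g <- head$const$g; dims <- head$const$dim
    b <- nrow(pooled)
    mu <- numeric(b); var <- numeric(b)
    per_dim <- vector("list", dims)
    for (d in seq_len(dims)) {
      ls <- exp(p$log_ls[d]); os <- exp(p$log_os[d])
      kp <- kernel_params(ls, os, 1)
      kuu <- rbf_kernel(head$const$grid, head$const$grid, kp)
      l <- chol_lower(kuu, GP_JITTER)
      xd <- pmin(pmax(pooled[, d], head$const$grid[1]),
                 head$const$grid[g])
      interp <- kiss_interpolation(xd, head$const$grid)
      w <- interp_matrix(interp, g)             # G x B
      a <- crossprod(l, w)                      # L^T W
      cmat <- head_cfactor(p$c_off[, , d], p$c_log_diag[, d])
      cta <- crossprod(cmat, a)
      mu <- mu + drop(crossprod(a, p$vm[, d]))
      var <- var + os - colSums(a^2) + colSums(cta^2)
      per_dim[[d]] <- list(l = l, w = w, a = a, cmat = cmat, cta = cta,
                           interp = interp, kp = kp, kuu = kuu)
    }
    var <- pmax(var, VAR_FLOOR)
    list(mean = mu, var = var,
         cache = list(type = "kiss", x = pooled, per_dim = per_dim))
  }
}

#' Marginalise a logistic likelihood over a Gaussian latent
#'
#' `E[sigmoid(f)]` for `f ~ N(mean, var)` by Gauss-Hermite quadrature;
#' the predictive class-1 probability of a GP classifier.
#' @param mean,var latent marginal moments (`var >= 0`).
#' @return probabilities in (0, 1).
#' @export
latent_to_probability <- function(mean, var) {
  if (any(var < 0)) stop("latent variance must be non-negative")
  gauss_expected_sigmoid(mean, var, GH_ORDER)
}

#' Stochastic variational classification ELBO of a GP head
#'
#' `N/B * sum_i E_q[log Bernoulli(y_i | sigmoid(f_i))] - KL(q || N(0, I))`
#' with the per-point expectation computed by Gauss-Hermite quadrature.
#'
#' @param pooled B x dim pooled features; `labels` in `{0,1}`.
#' @param head a `gp_head`.
#' @param n_total dataset size N the batch term is scaled to.
#' @param order quadrature order.
#' @return scalar ELBO value.
#' @export
svgp_classification_elbo <- function(pooled, labels, head, n_total = length(labels),
                                     order = GH_ORDER) {
  if (order < 1) stop("quadrature order must be at least 1")
  lat <- predictive_latent(pooled, head)
  e <- gauss_expected_bernoulli_ll(labels, lat$mean, lat$var, order)
  n_total / length(labels) * sum(e$value) - gp_head_kl(head)
}

# Adjoint of the Cholesky factorisation: given K = L L^T and dL, return
# the symmetric dK (Murray 2016 level-3 formula).
chol_adjoint <- function(l, lbar) {
  p <- crossprod(l, lbar)               # L^T Lbar
  p[upper.tri(p)] <- 0
  diag(p) <- diag(p) / 2
  ilt <- backsolve(t(l), diag(nrow(l))) # (L^T)^{-1}
  s <- ilt %*% p %*% t(ilt)
  (s + t(s)) / 2
}

# Backward pass through predictive_latent. gmu/gvar are dLoss/dmean and
# dLoss/dvar; klw scales the KL contribution added to the variational
# parameters. Returns parameter gradients and dLoss/dpooled.
gp_head_backward <- function(head, cache, gmu, gvar, klw = 0) {
  p <- head$params
  if (cache$type == "svgp") {
    a <- cache$a; cmat <- cache$cmat; l <- cache$l
    kuf <- cache$kuf; kuu <- cache$kuu
    ls <- cache$kp$lengthscale; os <- cache$kp$outputscale
    x <- cache$x; z <- p$z
    # variational mean / factor
    dvm <- drop(a %*% gmu)
    a_scaled <- sweep(a, 2, gvar, "*")
    dc <- 2 * (a_scaled %*% t(a)) %*% cmat
    if (klw > 0) {
      dvm <- dvm + klw * p$vm
      dkl_c <- cmat; diag(dkl_c) <- diag(dkl_c) - 1 / diag(cmat)
      dc <- dc + klw * dkl_c
    }
    cg <- cfactor_grads(dc, p$c_log_diag)
    # dA from mu and var terms
    da <- outer(p$vm, gmu) - 2 * a_scaled + 2 * cmat %*% crossprod(cmat, a_scaled)
    dkuf <- backsolve(t(l), da)
    dl <- -dkuf %*% t(a)
    dkuu <- chol_adjoint(l, dl)
    # kernel-parameter and location gradients
    gf <- dkuf * kuf
    gu <- dkuu * kuu
    sq_uf <- -2 * log(pmax(kuf / os, 1e-300)) * ls^2   # squared distances
    sq_uu <- -2 * log(pmax(kuu / os, 1e-300)) * ls^2
    dlog_ls <- (sum(gf * sq_uf) + sum(gu * sq_uu)) / ls^2
    dlog_os <- sum(gf) + sum(gu) + os * sum(gvar)
    dx <- (crossprod(gf, z) - x * colSums(gf)) / ls^2
    dz <- (gf %*% x - z * rowSums(gf)) / ls^2 +
      (gu %*% z - z * rowSums(gu)) / ls^2 +
      (crossprod(gu, z) - z * colSums(gu)) / ls^2
    grads <- list(z = dz, log_ls = dlog_ls, log_os = dlog_os,
                  vm = dvm, c_off = cg$c_off, c_log_diag = cg$c_log_diag)
    list(grads = grads, dx = dx)
  } else {
    g <- head$const$g; dims <- head$const$dim
    grid <- head$const$grid
    b <- length(gmu)
    dx <- matrix(0, b, dims)
    grads <- list(log_ls = numeric(dims), log_os = numeric(dims),
                  vm = p$vm * 0, c_off = p$c_off * 0,
                  c_log_diag = p$c_log_diag * 0)
    for (d in seq_len(dims)) {
      pd <- cache$per_dim[[d]]
      a <- pd$a; cmat <- pd$cmat; l <- pd$l; w <- pd$w
      ls <- pd$kp$lengthscale; os <- pd$kp$outputscale
      dvm <- drop(a %*% gmu)
      a_scaled <- sweep(a, 2, gvar, "*")
      dc <- 2 * (a_scaled %*% t(a)) %*% cmat
      if (klw > 0) {
        dvm <- dvm + klw * p$vm[, d]
        dkl_c <- cmat; diag(dkl_c) <- diag(dkl_c) - 1 / diag(cmat)
        dc <- dc + klw * dkl_c
      }
      cg <- cfactor_grads(dc, p$c_log_diag[, d])
      da <- outer(p$vm[, d], gmu) - 2 * a_scaled +
        2 * cmat %*% crossprod(cmat, a_scaled)
      # A = L^T W  =>  dW = L dA, dL = W dA^T
      dw <- l %*% da
      dl <- w %*% t(da)
      dkuu <- chol_adjoint(l, dl)
      gu <- dkuu * pd$kuu
      sq_uu <- outer(grid, grid, "-")^2
      grads$log_ls[d] <- sum(gu * sq_uu) / ls^2
      grads$log_os[d] <- sum(gu) + os * sum(gvar)
      grads$vm[, d] <- dvm
      grads$c_off[, , d] <- cg$c_off
      grads$c_log_diag[, d] <- cg$c_log_diag
      # input gradient through the interpolation weights
      idx <- pd$interp$idx
      for (i in seq_len(b)) {
        lo <- idx[i, 1]; hi <- idx[i, 2]
        delta <- grid[hi] - grid[lo]
        xi <- cache$x[i, d]
        if (xi > grid[1] && xi < grid[g]) {
          dt <- (dw[hi, i] - dw[lo, i]) / delta
          dx[i, d] <- dx[i, d] + dt
        }
      }
    }
    list(grads = grads, dx = dx)
  }
}
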