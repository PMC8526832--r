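# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force pair counting for AUROC, numeric
# quadrature for KL integrals, dense solve()-based Gaussian evidence, and
# central finite differences for gradients.

# AUROC by exhaustive comparison of every positive/negative pair.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# KL(N(mu_f, sd_f^2) || N(mu_t, sd_t^2)) by adaptive quadrature of the
# integrand q(x) log(q(x)/p(x)).
quadrature_gaussian_kl <- function(mu_f, sd_f, mu_t, sd_t) {
  integrand <- function(x) {
    q <- stats::dnorm(x, mu_f, sd_f)
    lr <- stats::dnorm(x, mu_f, sd_f, log = TRUE) -
      stats::dnorm(x, mu_t, sd_t, log = TRUE)
    q * lr
  }
  stats::integrate(integrand, mu_f - 12 * sd_f, mu_f + 12 * sd_f,
                   rel.tol = 1e-10)$value
}

# Exact GP evidence via dense solve() and determinant() (no Cholesky).
dense_gp_log_marginal <- function(x, y, params) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(x)
  kn <- rbf_kernel(x, x, params) + diag(params$noise_sd^2, n)
  -0.5 * drop(t(y) %*% solve(kn, y)) -
    0.5 * as.numeric(determinant(kn, logarithm = TRUE)$modulus) -
    n / 2 * log(2 * pi)
}

# Central finite difference of f at x (scalar-valued f, vector x).
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Finite-difference check of a gradient tree against a loss closure that
# re-seeds its own randomness. Samples up to `per_leaf` coordinates per
# leaf; returns the worst relative error.
fd_check_tree <- function(loss_fn, params, grads, per_leaf = 4L, h = 1e-5) {
  set_leaf <- function(tree, path, i, v) {
    if (length(path) == 0) { tree[i] <- v; return(tree) }
    tree[[path[1]]] <- set_leaf(tree[[path[1]]], path[-1], i, v)
    tree
  }
  flat_p <- bgpseq:::tree_leaves(params)
  flat_g <- bgpseq:::tree_leaves(grads)
  worst <- 0
  for (nm in names(flat_p)) {
    p <- flat_p[[nm]]; g <- flat_g[[nm]]
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    idx <- if (length(p) > per_leaf) sample(length(p), per_leaf) else seq_along(p)
    for (i in idx) {
      fd <- (loss_fn(set_leaf(params, path, i, p[i] + h)) -
               loss_fn(set_leaf(params, path, i, p[i] - h))) / (2 * h)
      worst <- max(worst, abs(fd - g[i]) / max(1, abs(fd), abs(g[i])))
    }
  }
  worst
}

# Multivariate Gaussian KL(N(m, S) || N(0, I)) via generic dense algebra.
dense_whitened_kl <- function(m, s) {
  k <- length(m)
  0.5 * (sum(diag(s)) + sum(m^2) - k -
           as.numeric(determinant(s, logarithm = TRUE)$modulus))
}
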