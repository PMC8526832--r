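# RBF kernel, the exact-GP regression evidence, the Titsias variational
# free energy for sparse GPs, and structured kernel interpolation (KISS):
# local linear interpolation of cross-covariances onto a fixed 1-D grid.

#' Kernel hyperparameters
#' @param lengthscale positive scalar (shared across input dimensions).
#' @param outputscale positive scalar variance `k(x,x)`.
#' @param noise_sd observation noise sd (regression only).
#' @return a `kernel_params` object.
#' @export
kernel_params <- function(lengthscale = 1, outputscale = 1, noise_sd = 0.1) {
  if (lengthscale <= 0 || outputscale <= 0 || noise_sd <= 0)
    stop("kernel parameters must be strictly positive")
  structure(list(lengthscale = lengthscale, outputscale = outputscale,
                 noise_sd = noise_sd), class = "kernel_params")
}

#' Radial basis function (squared-exponential) kernel matrix
#'
#' `K[i, j] = outputscale * exp(-||x_i - z_j||^2 / (2 lengthscale^2))`.
#'
#' @param x,z numeric matrices with one row per point (vectors are treated
#'   as single 1-D points per element when `drop = TRUE` via `as_points`).
#' @param params a `kernel_params`.
#' @return `nrow(x)` by `nrow(z)` covariance matrix.
#' @export
rbf_kernel <- function(x, z, params = kernel_params()) {
  x <- as_points(x); z <- as_points(z)
  if (ncol(x) != ncol(z)) stop("x and z must share dimensionality")
  sq <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
  sq[sq < 0] <- 0
  params$outputscale * exp(-0.5 * sq / params$lengthscale^2)
}

as_points <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

#' Exact GP regression log marginal likelihood
#'
#' Dense-algebra evidence `-1/2 y' Kn^-1 y - 1/2 log|Kn| - N/2 log(2 pi)`
#' with `Kn = Kff + noise_sd^2 I`. Intended as the small-n oracle against
#' which the sparse bound is checked.
#'
#' @param x training inputs (matrix, rows = points).
#' @param y numeric response vector.
#' @param params a `kernel_params`.
#' @return scalar log marginal likelihood.
#' @export
exact_gp_log_marginal <- function(x, y, params = kernel_params()) {
  x <- as_points(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  kn <- rbf_kernel(x, x, params) + diag(params$noise_sd^2, n)
  ch <- tryCatch(chol(kn), error = function(e)
    stop("covariance is numerically singular; add jitter or increase noise_sd"))
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
}

# Cholesky with escalating jitter; returns lower-triangular factor.
chol_lower <- function(k, jitter = 1e-6) {
  n <- nrow(k)
  for (j in jitter * 10^(0:6)) {
    ch <- tryCatch(chol(k + diag(j, n)), error = function(e) NULL)
    if (!is.null(ch)) {
      if (j > jitter) warning(sprintf("Cholesky needed inflated jitter %.1e", j))
      return(t(ch))
    }
  }
  stop("Cholesky failed even with inflated jitter")
}

#' Variational free energy of a sparse GP regression
#'
#' The collapsed evidence lower bound
#' `-1/2 y' Qn^-1 y - 1/2 log|Qn| - N/2 log(2 pi) - t/(2 noise_sd^2)`,
#' where `Qff = Kuf' Kuu^-1 Kuf`, `Qn = Qff + noise_sd^2 I` and
#' `t = tr(Kff - Qff)` is the Nystrom residual trace. Never exceeds the
#' exact log marginal likelihood, with equality when the inducing set
#' equals the training inputs.
#'
#' @param x training inputs; `y` responses.
#' @param inducing matrix of inducing point locations (rows = points).
#' @param params a `kernel_params`.
#' @param jitter added to `Kuu` before factorisation.
#' @return scalar lower bound on the log marginal likelihood.
#' @export
sparse_free_energy <- function(x, y, inducing, params = kernel_params(),
                               jitter = 1e-10) {
  x <- as_points(x); inducing <- as_points(inducing)
  n <- nrow(x)
  kuu <- rbf_kernel(inducing, inducing, params)
  kuf <- rbf_kernel(inducing, x, params)
  l <- chol_lower(kuu, jitter)
  a <- forwardsolve(l, kuf)                       # M x N, Qff = A'A
  qn <- crossprod(a) + diag(params$noise_sd^2, n)
  ch <- chol(qn)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  trace_resid <- n * params$outputscale - sum(a^2)
  trace_resid <- max(trace_resid, 0)
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi) -
    trace_resid / (2 * params$noise_sd^2)
}

#' Build a 1-D interpolation grid
#' @param lower,upper grid range; `n` number of points.
#' @return strictly increasing numeric vector.
#' @export
kiss_grid <- function(lower = -1.1, upper = 1.1, n = 64L) {
  stopifnot(n >= 2L, upper > lower)
  seq(lower, upper, length.out = n)
}

#' Local linear interpolation weights onto a 1-D grid
#'
#' For each input, returns the indices of the two adjacent grid points and
#' weights proportional to the opposite-interval distances; the weights of
#' each row are non-negative and sum to one. Inputs outside the grid are
#' clamped to the boundary with a warning.
#'
#' @param x numeric vector of 1-D inputs.
#' @param grid strictly increasing grid vector.
#' @return list with integer matrices `idx` (n x 2) and numeric `w` (n x 2).
#' @export
kiss_interpolation <- function(x, grid) {
  if (length(grid) < 2L) stop("grid must contain at least two points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  out_of_range <- x < grid[1] | x > grid[length(grid)]
  if (any(out_of_range)) {
    warning(sprintf("%d input(s) outside the grid were clamped to its boundary",
                    sum(out_of_range)))
    x <- pmin(pmax(x, grid[1]), grid[length(grid)])
  }
  lo <- findInterval(x, grid, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), length(grid) - 1L)
  hi <- lo + 1L
  t <- (x - grid[lo]) / (grid[hi] - grid[lo])
  idx <- cbind(lo, hi); w <- cbind(1 - t, t)
  dimnames(idx) <- NULL; dimnames(w) <- NULL
  list(idx = idx, w = w)
}

#' KISS approximation of the Nystrom covariance
#'
#' `Qff ~ W' Kuu W` with the sparse interpolation matrix `W`; the dense
#' `Kff` is never formed.
#'
#' @param x numeric vector of 1-D inputs.
#' @param grid 1-D inducing grid.
#' @param params a `kernel_params`.
#' @return `length(x)` square approximate covariance matrix.
#' @export
kiss_q_ff <- function(x, grid, params = kernel_params()) {
  if (length(grid) == 0L) stop("grid is empty")
  interp <- kiss_interpolation(x, grid)
  w <- interp_matrix(interp, length(grid))        # G x n
  kuu <- rbf_kernel(grid, grid, params)
  crossprod(w, kuu %*% w)
}

# Dense G x n interpolation matrix from sparse rows (desk scale).
interp_matrix <- function(interp, g) {
  n <- nrow(interp$idx)
  w <- matrix(0, g, n)
  for (i in seq_len(n)) {
    w[interp$idx[i, 1], i] <- w[interp$idx[i, 1], i] + interp$w[i, 1]
    w[interp$idx[i, 2], i] <- w[interp$idx[i, 2], i] + interp$w[i, 2]
  }
  w
}
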