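# Parameters are stored as nested named lists whose leaves are numeric
# arrays; gradients mirror the same shape. These helpers walk two or three
# trees in lockstep, which is all the optimizer and the variational
# reparameterisation need.

is_leaf <- function(x) is.numeric(x)

tree_map <- function(f, a) {
  if (is_leaf(a)) return(f(a))
  out <- lapply(a, function(el) tree_map(f, el))
  names(out) <- names(a)
  out
}

tree_map2 <- function(f, a, b) {
  if (is_leaf(a)) return(f(a, b))
  out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
  names(out) <- names(a)
  out
}

tree_zero <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)

# Flatten leaves into a named list "path.to.leaf" -> array
tree_leaves <- function(a, prefix = NULL) {
  if (is_leaf(a)) {
    out <- list(a); names(out) <- paste(prefix, collapse = ".")
    return(out)
  }
  out <- list()
  for (nm in names(a)) out <- c(out, tree_leaves(a[[nm]], c(prefix, nm)))
  out
}

# Largest absolute leaf value, for divergence diagnostics
tree_max_abs <- function(a) {
  max(vapply(tree_leaves(a), function(x) max(abs(x), 0), numeric(1)), 0)
}

#' Adam optimizer state
#'
#' Standard Adam with bias correction; weight decay is added to the
#' gradient (coupled L2) only for leaves selected by `decay_filter`, so
#' variational scale parameters, normalisation gains/biases and GP
#' hyperparameters can be exempted.
#'
#' @param params parameter tree the optimizer will be stepping.
#' @param lr learning rate; `beta1`, `beta2`, `eps` the usual moments.
#' @param weight_decay L2 coefficient.
#' @param decay_filter function(path string) -> logical; default decays
#'   only matrix-valued weights whose path does not mention `rho`, `bias`,
#'   `ln` or the GP head.
#' @return an `adam_state` object.
#' @export
adam_init <- function(params, lr = 3e-5, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.01,
                      decay_filter = default_decay_filter) {
  structure(list(m = tree_zero(params), v = tree_zero(params), t = 0L,
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, decay_filter = decay_filter),
            class = "adam_state")
}

default_decay_filter <- function(path) {
  grepl("(^|\\.)(wq|wk|wv|wo|w1|w2|wp|w|mean|table)$", path) &&
    !grepl("rho|gp|ln|log_", path)
}

#' One Adam step
#' @param state an `adam_state`.
#' @param params current parameter tree.
#' @param grads gradient tree of the same shape.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  walk <- function(p, g, m, v, path) {
    if (is_leaf(p)) {
      if (state$weight_decay > 0 && state$decay_filter(path))
        g <- g + state$weight_decay * p
      m <- state$beta1 * m + (1 - state$beta1) * g
      v <- state$beta2 * v + (1 - state$beta2) * g^2
      step <- state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
      return(list(p = p - step, m = m, v = v))
    }
    ps <- p; ms <- m; vs <- v
    for (nm in names(p)) {
      sub <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                  paste(path, nm, sep = "."))
      ps[[nm]] <- sub$p; ms[[nm]] <- sub$m; vs[[nm]] <- sub$v
    }
    list(p = ps, m = ms, v = vs)
  }
  res <- walk(params, grads, state$m, state$v, "")
  state$m <- res$m; state$v <- res$v
  list(params = res$p, state = state)
}
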