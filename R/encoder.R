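# BEHRT-style sequence encoder: four summed embedding tables (code, age,
# segment/visit-parity, position/visit-rank), a stack of post-norm
# self-attention transformer layers, and a tanh pooling of the first
# (CLS) position. Forward passes keep a cache so the matching backward
# pass can return exact gradients for every weight tensor; the encoder is
# trained by hand-rolled reverse-mode differentiation rather than an
# external autodiff framework.

LN_EPS <- 1e-6
NEG_INF <- -1e9

#' Encoder configuration
#'
#' @param vocab_size total number of code tokens (including specials).
#' @param max_seq_len maximum token sequence length.
#' @param hidden_size transformer width; must be divisible by `n_heads`.
#' @param n_layers,n_heads,intermediate_size transformer shape.
#' @param dropout dropout rate in `[0, 1)`; applied during training only.
#' @param pooled_size width of the pooled CLS representation fed to the
#'   classifier head.
#' @param embedding_mode `"deterministic"` or `"stochastic"` (mean-field
#'   posteriors over all four embedding tables).
#' @param age_vocab,pos_vocab sizes of the age-in-years and visit-rank
#'   lookup tables.
#' @param truncate if `TRUE`, overlength sequences are clipped from the
#'   start (keeping CLS); otherwise they raise an error.
#' @return an `encoder_config` object.
#' @export
encoder_config <- function(vocab_size,
                           max_seq_len = 64L,
                           hidden_size = 32L,
                           n_layers = 2L,
                           n_heads = 2L,
                           intermediate_size = 64L,
                           dropout = 0.1,
                           pooled_size = hidden_size,
                           embedding_mode = c("deterministic", "stochastic"),
                           age_vocab = 111L,
                           pos_vocab = 64L,
                           truncate = FALSE) {
  embedding_mode <- match.arg(embedding_mode)
  if (hidden_size %% n_heads != 0) stop("hidden_size must divide by n_heads")
  if (pooled_size > hidden_size) stop("pooled_size must not exceed hidden_size")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(vocab_size = as.integer(vocab_size),
                 max_seq_len = as.integer(max_seq_len),
                 hidden_size = as.integer(hidden_size),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 intermediate_size = as.integer(intermediate_size),
                 dropout = dropout,
                 pooled_size = as.integer(pooled_size),
                 embedding_mode = embedding_mode,
                 age_vocab = as.integer(age_vocab),
                 pos_vocab = as.integer(pos_vocab),
                 truncate = truncate),
            class = "encoder_config")
}

#' Reference configuration matching the full-scale study architecture
#'
#' Hidden size 150, 4 layers, 6 heads, intermediate size 108, dropout
#' 0.29, maximum sequence length 256; pooled size 150 for linear heads
#' and 24 for GP heads.
#' @param vocab_size code vocabulary size.
#' @param pooled_size 150 (linear) or 24 (GP heads).
#' @inheritParams encoder_config
#' @export
paper_encoder_config <- function(vocab_size, pooled_size = 24L,
                                 embedding_mode = "deterministic") {
  encoder_config(vocab_size, max_seq_len = 256L, hidden_size = 150L,
                 n_layers = 4L, n_heads = 6L, intermediate_size = 108L,
                 dropout = 0.29, pooled_size = pooled_size,
                 embedding_mode = embedding_mode)
}

#' Desk-scale configuration for CPU experimentation and testing
#' @inheritParams paper_encoder_config
#' @export
desk_encoder_config <- function(vocab_size, pooled_size = 8L,
                                embedding_mode = "deterministic") {
  encoder_config(vocab_size, max_seq_len = 40L, hidden_size = 16L,
                 n_layers = 2L, n_heads = 2L, intermediate_size = 32L,
                 dropout = 0.1, pooled_size = pooled_size,
                 embedding_mode = embedding_mode, pos_vocab = 16L)
}

rand_mat <- function(nr, nc, sd = 0.1) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# Initialise all encoder weights from the current RNG stream. Embedding
# tables are plain matrices in deterministic mode and mean-field
# posteriors (initial sd `init_sd`) in stochastic mode.
init_encoder_params <- function(config, init_sd = 0.05) {
  h <- config$hidden_size
  make_table <- function(v) {
    tab <- rand_mat(v, h, sd = 0.3)
    if (config$embedding_mode == "stochastic") mean_field_posterior(tab, init_sd)
    else tab
  }
  emb <- list(code = make_table(config$vocab_size),
              age = make_table(config$age_vocab),
              seg = make_table(2L),
              pos = make_table(config$pos_vocab))
  layer <- function() {
    list(wq = rand_mat(h, h), bq = numeric(h),
         wk = rand_mat(h, h), bk = numeric(h),
         wv = rand_mat(h, h), bv = numeric(h),
         wo = rand_mat(h, h), bo = numeric(h),
         ln1_g = rep(1, h), ln1_b = numeric(h),
         w1 = rand_mat(h, config$intermediate_size),
         b1 = numeric(config$intermediate_size),
         w2 = rand_mat(config$intermediate_size, h),
         b2 = numeric(h),
         ln2_g = rep(1, h), ln2_b = numeric(h))
  }
  layers <- stats::setNames(replicate(config$n_layers, layer(), simplify = FALSE),
                            paste0("l", seq_len(config$n_layers)))
  list(emb = emb,
       emb_ln = list(g = rep(1, h), b = numeric(h)),
       layers = layers,
       pool = list(wp = rand_mat(h, config$pooled_size), bp = numeric(config$pooled_size)))
}

# ---- batching -------------------------------------------------------------

# Pad (or clip) a list of patient_records into id matrices. PAD has id 0.
pad_batch <- function(records, config) {
  clip <- function(r) {
    len <- length(r$codes)
    if (len <= config$max_seq_len) return(r)
    if (!config$truncate)
      stop(sprintf("sequence length %d exceeds max_seq_len %d (set truncate = TRUE to clip)",
                   len, config$max_seq_len))
    keep <- (len - config$max_seq_len + 2L):len
    r$codes <- c(r$codes[1L], r$codes[keep])
    r$ages <- c(r$ages[keep][1L], r$ages[keep])
    r$segments <- c(r$segments[keep][1L], r$segments[keep])
    r$positions <- c(r$positions[keep][1L], r$positions[keep])
    r
  }
  records <- lapply(records, clip)
  lens <- vapply(records, function(r) length(r$codes), integer(1))
  l <- max(lens)
  b <- length(records)
  codes <- matrix(0L, b, l); ages <- matrix(0L, b, l)
  segs <- matrix(0L, b, l); pos <- matrix(0L, b, l)
  for (i in seq_len(b)) {
    r <- records[[i]]
    if (any(r$codes >= config$vocab_size) || any(r$codes < 0L))
      stop("code id out of range in the code embedding layer")
    if (any(r$segments > 1L) || any(r$segments < 0L))
      stop("segment id out of range in the segment embedding layer")
    idx <- seq_len(lens[i])
    codes[i, idx] <- r$codes
    ages[i, idx] <- pmin(r$ages, config$age_vocab - 1L)
    segs[i, idx] <- r$segments
    pos[i, idx] <- pmin(r$positions, config$pos_vocab - 1L)
  }
  mask <- matrix(0, b, l)
  for (i in seq_len(b)) mask[i, seq_len(lens[i])] <- 1
  list(codes = codes, ages = ages, segs = segs, pos = pos,
       mask = mask, b = b, l = l, lens = lens)
}

#' Embed one patient sequence
#'
#' Element `t` of the result is the sum of the four table rows selected by
#' the token's code, (bucketed) age, segment and position ids.
#'
#' @param record a `patient_record`.
#' @param tables list with matrices `code`, `age`, `seg`, `pos` (one
#'   sampled or point value per table; rows index ids from 0).
#' @return a `length(record$codes)` x hidden matrix.
#' @export
embed_sequence <- function(record, tables) {
  check <- function(ids, tab, layer) {
    if (any(ids < 0L) || any(ids >= nrow(tab)))
      stop(sprintf("id out of range in the %s embedding layer", layer))
  }
  check(record$codes, tables$code, "code")
  check(record$segments, tables$seg, "segment")
  age <- pmin(record$ages, nrow(tables$age) - 1L)
  pos <- pmin(record$positions, nrow(tables$pos) - 1L)
  tables$code[record$codes + 1L, , drop = FALSE] +
    tables$age[age + 1L, , drop = FALSE] +
    tables$seg[record$segments + 1L, , drop = FALSE] +
    tables$pos[pos + 1L, , drop = FALSE]
}

# ---- layer primitives (forward + backward) --------------------------------

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_bwd <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

make_dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_mask <- function(x, m) if (is.null(m)) x else x * m

# ---- encoder forward / backward -------------------------------------------

# weights: point-valued parameter tree (embedding tables already drawn).
# batch: output of pad_batch. Returns pooled features and a backward cache.
encoder_forward <- function(weights, batch, config, training = FALSE) {
  h <- config$hidden_size
  nh <- config$n_heads
  dh <- h %/% nh
  b <- batch$b; l <- batch$l
  p <- if (training) config$dropout else 0

  ids <- list(code = as.vector(t(batch$codes)) + 1L,
              age = as.vector(t(batch$ages)) + 1L,
              seg = as.vector(t(batch$segs)) + 1L,
              pos = as.vector(t(batch$pos)) + 1L)
  # rows ordered (seq1 pos1..L, seq2 pos1..L, ...)
  x0 <- weights$emb$code[ids$code, , drop = FALSE] +
    weights$emb$age[ids$age, , drop = FALSE] +
    weights$emb$seg[ids$seg, , drop = FALSE] +
    weights$emb$pos[ids$pos, , drop = FALSE]
  ln0 <- layernorm_fwd(x0, weights$emb_ln$g, weights$emb_ln$b)
  drop0 <- make_dropout_mask(nrow(x0), h, p)
  x <- apply_mask(ln0$y, drop0)

  key_mask <- lapply(seq_len(b), function(i) batch$mask[i, ] == 1)
  rows_of <- function(i) ((i - 1L) * l + 1L):(i * l)

  layer_caches <- vector("list", config$n_layers)
  for (li in seq_len(config$n_layers)) {
    w <- weights$layers[[li]]
    xin <- x
    q <- xin %*% w$wq + rep(w$bq, each = nrow(xin))
    k <- xin %*% w$wk + rep(w$bk, each = nrow(xin))
    v <- xin %*% w$wv + rep(w$bv, each = nrow(xin))
    ctx <- matrix(0, nrow(xin), h)
    att <- vector("list", b)
    for (i in seq_len(b)) {
      ri <- rows_of(i)
      keep <- key_mask[[i]]
      att[[i]] <- vector("list", nh)
      for (hd in seq_len(nh)) {
        cols <- ((hd - 1L) * dh + 1L):(hd * dh)
        s <- tcrossprod(q[ri, cols, drop = FALSE], k[ri, cols, drop = FALSE]) / sqrt(dh)
        if (!all(keep)) s[, !keep] <- NEG_INF
        s <- s - apply(s, 1, max)
        a <- exp(s)
        a <- a / rowSums(a)
        att[[i]][[hd]] <- a
        ctx[ri, cols] <- a %*% v[ri, cols, drop = FALSE]
      }
    }
    o <- ctx %*% w$wo + rep(w$bo, each = nrow(xin))
    drop_o <- make_dropout_mask(nrow(xin), h, p)
    o <- apply_mask(o, drop_o)
    ln1 <- layernorm_fwd(xin + o, w$ln1_g, w$ln1_b)
    x1 <- ln1$y
    fpre <- x1 %*% w$w1 + rep(w$b1, each = nrow(x1))
    fact <- gelu_fwd(fpre)
    g2 <- fact %*% w$w2 + rep(w$b2, each = nrow(x1))
    drop_g <- make_dropout_mask(nrow(x1), h, p)
    g2 <- apply_mask(g2, drop_g)
    ln2 <- layernorm_fwd(x1 + g2, w$ln2_g, w$ln2_b)
    layer_caches[[li]] <- list(xin = xin, q = q, k = k, v = v, att = att,
                               ctx = ctx, drop_o = drop_o, ln1 = ln1, x1 = x1,
                               fpre = fpre, fact = fact, drop_g = drop_g,
                               ln2 = ln2)
    x <- ln2$y
  }

  first_rows <- (seq_len(b) - 1L) * l + 1L
  pooled_pre <- x[first_rows, , drop = FALSE] %*% weights$pool$wp +
    rep(weights$pool$bp, each = b)
  pooled <- tanh(pooled_pre)

  list(pooled = pooled,
       cache = list(config = config, batch = batch, ids = ids, x0 = x0,
                    ln0 = ln0, drop0 = drop0, layers = layer_caches,
                    xfinal = x, first_rows = first_rows, pooled = pooled,
                    weights = weights, key_mask = key_mask))
}

# Backward pass: dpooled is B x pooled_size. Returns a gradient tree with
# the same layout as the weights (embedding gradients as plain matrices).
encoder_backward <- function(cache, dpooled) {
  config <- cache$config
  weights <- cache$weights
  h <- config$hidden_size
  nh <- config$n_heads
  dh <- h %/% nh
  b <- cache$batch$b; l <- cache$batch$l
  rows_of <- function(i) ((i - 1L) * l + 1L):(i * l)

  grads <- tree_zero_like_weights(weights)

  dpre <- dpooled * (1 - cache$pooled^2)
  xf_first <- cache$xfinal[cache$first_rows, , drop = FALSE]
  grads$pool$wp <- crossprod(xf_first, dpre)
  grads$pool$bp <- colSums(dpre)
  dx <- matrix(0, nrow(cache$xfinal), h)
  dx[cache$first_rows, ] <- dpre %*% t(weights$pool$wp)

  for (li in rev(seq_len(config$n_layers))) {
    w <- weights$layers[[li]]
    cl <- cache$layers[[li]]
    # LN2
    ln2b <- layernorm_bwd(dx, cl$ln2, w$ln2_g)
    grads$layers[[li]]$ln2_g <- ln2b$dg
    grads$layers[[li]]$ln2_b <- ln2b$db
    dres2 <- ln2b$dx                    # gradient w.r.t. (x1 + g2)
    dg2 <- apply_mask(dres2, cl$drop_g)
    grads$layers[[li]]$w2 <- crossprod(cl$fact, dg2)
    grads$layers[[li]]$b2 <- colSums(dg2)
    dfact <- dg2 %*% t(w$w2)
    dfpre <- dfact * gelu_bwd(cl$fpre)
    grads$layers[[li]]$w1 <- crossprod(cl$x1, dfpre)
    grads$layers[[li]]$b1 <- colSums(dfpre)
    dx1 <- dres2 + dfpre %*% t(w$w1)
    # LN1
    ln1b <- layernorm_bwd(dx1, cl$ln1, w$ln1_g)
    grads$layers[[li]]$ln1_g <- ln1b$dg
    grads$layers[[li]]$ln1_b <- ln1b$db
    dres1 <- ln1b$dx                    # gradient w.r.t. (xin + o)
    do <- apply_mask(dres1, cl$drop_o)
    grads$layers[[li]]$wo <- crossprod(cl$ctx, do)
    grads$layers[[li]]$bo <- colSums(do)
    dctx <- do %*% t(w$wo)
    dq <- matrix(0, nrow(dx), h); dk <- matrix(0, nrow(dx), h)
    dv <- matrix(0, nrow(dx), h)
    for (i in seq_len(b)) {
      ri <- rows_of(i)
      for (hd in seq_len(nh)) {
        cols <- ((hd - 1L) * dh + 1L):(hd * dh)
        a <- cl$att[[i]][[hd]]
        dctx_h <- dctx[ri, cols, drop = FALSE]
        da <- tcrossprod(dctx_h, cl$v[ri, cols, drop = FALSE])
        dv[ri, cols] <- dv[ri, cols] + crossprod(a, dctx_h)
        ds <- a * (da - rowSums(da * a))
        dq[ri, cols] <- dq[ri, cols] +
          ds %*% cl$k[ri, cols, drop = FALSE] / sqrt(dh)
        dk[ri, cols] <- dk[ri, cols] +
          crossprod(ds, cl$q[ri, cols, drop = FALSE]) / sqrt(dh)
      }
    }
    grads$layers[[li]]$wq <- crossprod(cl$xin, dq)
    grads$layers[[li]]$bq <- colSums(dq)
    grads$layers[[li]]$wk <- crossprod(cl$xin, dk)
    grads$layers[[li]]$bk <- colSums(dk)
    grads$layers[[li]]$wv <- crossprod(cl$xin, dv)
    grads$layers[[li]]$bv <- colSums(dv)
    dx <- dres1 + dq %*% t(w$wq) + dk %*% t(w$wk) + dv %*% t(w$wv)
  }

  dx <- apply_mask(dx, cache$drop0)
  ln0b <- layernorm_bwd(dx, cache$ln0, weights$emb_ln$g)
  grads$emb_ln$g <- ln0b$dg
  grads$emb_ln$b <- ln0b$db
  dx0 <- ln0b$dx
  for (tab in c("code", "age", "seg", "pos")) {
    agg <- rowsum(dx0, cache$ids[[tab]])
    gmat <- matrix(0, nrow(weights$emb[[tab]]), h)
    gmat[as.integer(rownames(agg)), ] <- agg
    grads$emb[[tab]] <- gmat
  }
  grads
}

tree_zero_like_weights <- function(weights) tree_map(function(x) x * 0, weights)

#' Encode a hidden-state sequence through the transformer stack
#'
#' Single-sequence convenience wrapper used for testing the contextual
#' layer in isolation; deterministic when `training = FALSE`.
#'
#' @param hidden L x hidden matrix of input embeddings.
#' @param config an `encoder_config`.
#' @param weights an encoder parameter tree with point-valued tables.
#' @param mask optional logical vector of real (non-PAD) positions.
#' @return L x hidden matrix of contextual vectors.
#' @export
encode <- function(hidden, config, weights, mask = NULL) {
  l <- nrow(hidden)
  if (l > config$max_seq_len && !config$truncate)
    stop(sprintf("sequence length %d exceeds max_seq_len %d (set truncate = TRUE to clip)",
                 l, config$max_seq_len))
  if (is.null(mask)) mask <- rep(TRUE, l)
  batch <- list(b = 1L, l = l, mask = matrix(as.numeric(mask), 1L, l),
                codes = matrix(0L, 1L, l), ages = matrix(0L, 1L, l),
                segs = matrix(0L, 1L, l), pos = matrix(0L, 1L, l),
                lens = sum(mask))
  # bypass the embedding lookup: run the layer stack directly
  run_layers_only(weights, hidden, batch, config)
}

run_layers_only <- function(weights, x, batch, config) {
  fake_cache <- encoder_forward_from_hidden(weights, x, batch, config)
  fake_cache$x
}

# Shared layer-stack forward used by encode(); no dropout, no cache.
encoder_forward_from_hidden <- function(weights, x, batch, config) {
  h <- config$hidden_size; nh <- config$n_heads; dh <- h %/% nh
  b <- batch$b; l <- batch$l
  rows_of <- function(i) ((i - 1L) * l + 1L):(i * l)
  for (li in seq_len(config$n_layers)) {
    w <- weights$layers[[li]]
    xin <- x
    q <- xin %*% w$wq + rep(w$bq, each = nrow(xin))
    k <- xin %*% w$wk + rep(w$bk, each = nrow(xin))
    v <- xin %*% w$wv + rep(w$bv, each = nrow(xin))
    ctx <- matrix(0, nrow(xin), h)
    for (i in seq_len(b)) {
      ri <- rows_of(i)
      keep <- batch$mask[i, ] == 1
      for (hd in seq_len(nh)) {
        cols <- ((hd - 1L) * dh + 1L):(hd * dh)
        s <- tcrossprod(q[ri, cols, drop = FALSE], k[ri, cols, drop = FALSE]) / sqrt(dh)
        if (!all(keep)) s[, !keep] <- NEG_INF
        s <- s - apply(s, 1, max)
        a <- exp(s); a <- a / rowSums(a)
        ctx[ri, cols] <- a %*% v[ri, cols, drop = FALSE]
      }
    }
    o <- ctx %*% w$wo + rep(w$bo, each = nrow(xin))
    x1 <- layernorm_fwd(xin + o, w$ln1_g, w$ln1_b)$y
    fact <- gelu_fwd(x1 %*% w$w1 + rep(w$b1, each = nrow(x1)))
    g2 <- fact %*% w$w2 + rep(w$b2, each = nrow(x1))
    x <- layernorm_fwd(x1 + g2, w$ln2_g, w$ln2_b)$y
  }
  list(x = x)
}

#' Pool the first (CLS) position of a contextual sequence
#'
#' Affine map plus tanh of element 0; output dimension `pooled_size`.
#' @param contextual L x hidden matrix.
#' @param pool list with `wp` (hidden x pooled) and `bp` (pooled).
#' @return pooled numeric vector, elements in (-1, 1).
#' @export
pool_first <- function(contextual, pool) {
  if (is.null(dim(contextual)) || nrow(contextual) < 1L)
    stop("cannot pool an empty sequence")
  tanh(drop(contextual[1L, , drop = FALSE] %*% pool$wp) + pool$bp)
}
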