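# Model variants, the joint training objective, the Adam training loop
# and Monte-Carlo predictive inference.
#
# Six variants are supported. DBGP couples stochastic embeddings with a
# KISS-GP head; BE / BO / BE+BO use a linear classifier with the named
# parameter groups stochastic; SPARSE_GP and KISS_GP put a GP head on a
# fully deterministic encoder.

MODEL_VARIANTS <- c("DBGP", "BE", "BO", "BE_BO", "SPARSE_GP", "KISS_GP")

#' Training configuration
#'
#' Defaults follow the full-scale training setup (Adam, batch 64, learning rate
#' 3e-5, weight decay 0.01, one weight draw per step); override the
#' learning rate and epochs for small-scale experiments.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size; `head_learning_rate` optionally
#'   gives the GP/classifier head its own rate.
#' @param weight_decay coupled L2 on encoder weight matrices (never on
#'   variational scales or GP hyperparameters).
#' @param epochs training epochs.
#' @param mc_train_draws weight draws per training step.
#' @param prior prior over stochastic weights (`prior_spec()`).
#' @param seed training seed (shuffling, dropout, weight draws).
#' @return a `training_config` object.
#' @export
training_config <- function(batch_size = 64L, learning_rate = 3e-5,
                            weight_decay = 0.01, epochs = 5L,
                            mc_train_draws = 1L, prior = prior_spec(),
                            head_learning_rate = NULL, seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 0, mc_train_draws >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 mc_train_draws = as.integer(mc_train_draws),
                 prior = prior,
                 head_learning_rate = head_learning_rate,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Assemble a model variant
#'
#' @param variant one of `"DBGP"`, `"BE"`, `"BO"`, `"BE_BO"`,
#'   `"SPARSE_GP"`, `"KISS_GP"`.
#' @param config an `encoder_config`; its `embedding_mode` is overridden
#'   to match the variant.
#' @param n_inducing free inducing points for the sparse-GP head.
#' @param grid_size grid points per pooled dimension for KISS heads.
#' @param init_seed seed for weight initialisation.
#' @param init_sd initial posterior sd of stochastic groups.
#' @return a `bgpseq_model`; its `report` field lists each parameter
#'   group with its size and whether it is stochastic.
#' @export
build_model <- function(variant = MODEL_VARIANTS, config,
                        n_inducing = 40L, grid_size = 64L,
                        init_seed = 1L, init_sd = 0.05) {
  variant <- match.arg(variant)
  stochastic_emb <- variant %in% c("DBGP", "BE", "BE_BO")
  stochastic_clf <- variant %in% c("BO", "BE_BO")
  head_type <- switch(variant,
                      DBGP = "kiss", KISS_GP = "kiss",
                      SPARSE_GP = "svgp", "linear")
  config$embedding_mode <- if (stochastic_emb) "stochastic" else "deterministic"
  with_seed(derive_seed(init_seed, paste0("init-", variant)), {
    enc <- init_encoder_params(config, init_sd)
    if (head_type == "linear") {
      w <- stats::rnorm(config$pooled_size, 0, 0.1)
      head <- if (stochastic_clf) {
        list(w = mean_field_posterior(w, init_sd),
             b = mean_field_posterior(0, init_sd))
      } else list(w = w, b = 0)
      head_const <- list(type = "linear", dim = config$pooled_size)
      head_params <- head
    } else {
      gp <- gp_head_init(head_type, dim = config$pooled_size,
                         n_inducing = n_inducing, grid_size = grid_size)
      head_const <- gp$const
      head_params <- gp$params
    }
    n_of <- function(x) sum(vapply(tree_leaves(x), length, integer(1)))
    report <- data.frame(
      group = c("embeddings", "encoder", "pooler", "classifier"),
      n_params = c(n_of(enc$emb), n_of(enc$layers) + n_of(enc$emb_ln),
                   n_of(enc$pool), n_of(head_params)),
      stochastic = c(stochastic_emb, FALSE, FALSE, stochastic_clf))
    structure(list(variant = variant, config = config,
                   head_type = head_type, head_const = head_const,
                   params = list(encoder = enc, head = head_params),
                   stochastic = list(embeddings = stochastic_emb,
                                     classifier = stochastic_clf),
                   report = report),
              class = "bgpseq_model")
  })
}

#' @export
print.bgpseq_model <- function(x, ...) {
  cat(sprintf("<bgpseq_model %s: %s head, hidden %d, %d layers>\n",
              x$variant, x$head_type, x$config$hidden_size, x$config$n_layers))
  print(x$report, row.names = FALSE)
  invisible(x)
}

# Draw point weights for one forward pass. Returns enc (tables as plain
# matrices), head weights, and the eps noise used for stochastic groups.
draw_model_weights <- function(model, deterministic = FALSE) {
  enc <- model$params$encoder
  eps <- list()
  if (model$stochastic$embeddings) {
    for (tab in names(enc$emb)) {
      post <- enc$emb[[tab]]
      if (deterministic) {
        enc$emb[[tab]] <- post$mean
      } else {
        d <- sample_weights(post)
        enc$emb[[tab]] <- d$w
        eps[[paste0("emb_", tab)]] <- d$eps
      }
    }
  }
  head <- model$params$head
  if (model$head_type == "linear" && model$stochastic$classifier) {
    for (nm in c("w", "b")) {
      post <- head[[nm]]
      if (deterministic) {
        head[[nm]] <- post$mean
      } else {
        d <- sample_weights(post)
        head[[nm]] <- d$w
        eps[[paste0("clf_", nm)]] <- d$eps
      }
    }
  }
  list(enc = enc, head = head, eps = eps)
}

# Sum of weight-KL terms over stochastic groups.
model_weight_kl <- function(model, prior = prior_spec()) {
  total <- 0
  if (model$stochastic$embeddings)
    for (tab in names(model$params$encoder$emb))
      total <- total + kl_to_prior(model$params$encoder$emb[[tab]], prior)
  if (model$head_type == "linear" && model$stochastic$classifier)
    for (nm in c("w", "b"))
      total <- total + kl_to_prior(model$params$head[[nm]], prior)
  total
}

# Full objective and gradient for one minibatch under one weight draw.
# loss = -( N/B * E[data loglik] - kl_gp/n_batches - pi_i * KL(q||p) )
model_loss_and_grad <- function(model, records, n_total, batch_index = 1L,
                                n_batches = 1L, prior = prior_spec(),
                                training = TRUE, compute_grad = TRUE) {
  labels <- vapply(records, function(r) r$label, integer(1))
  b <- length(records)
  draw <- draw_model_weights(model)
  batch <- pad_batch(records, model$config)
  fwd <- encoder_forward(draw$enc, batch, model$config, training = training)
  pooled <- fwd$pooled
  scale <- n_total / b
  pi_i <- minibatch_kl_weight(batch_index, n_batches)
  any_stochastic <- model$stochastic$embeddings || model$stochastic$classifier
  wkl <- if (any_stochastic) model_weight_kl(model, prior) else 0

  if (model$head_type == "linear") {
    logits <- bayesian_linear_forward(pooled, draw$head)
    ll <- labels * logits - log1pexp(logits)
    data_term <- scale * sum(ll)
    gp_kl <- 0
  } else {
    head <- list(const = model$head_const, params = model$params$head)
    lat <- predictive_latent(pooled, head)
    e <- gauss_expected_bernoulli_ll(labels, lat$mean, lat$var)
    data_term <- scale * sum(e$value)
    gp_kl <- gp_head_kl(head)
  }
  loss <- -(data_term - gp_kl / n_batches - pi_i * wkl)
  if (!is.finite(loss)) {
    diag_msg <- if (model$head_type != "linear")
      sprintf(" (lengthscale range %.3g..%.3g)",
              min(exp(model$params$head$log_ls)),
              max(exp(model$params$head$log_ls))) else ""
    stop("non-finite training loss; aborting", diag_msg)
  }
  if (!compute_grad) return(list(loss = loss, pooled = pooled))

  grads <- list(encoder = NULL, head = NULL)
  if (model$head_type == "linear") {
    dlogit <- -scale * (labels - sigmoid(logits))
    dpooled <- outer(dlogit, if (model$stochastic$classifier) draw$head$w else model$params$head$w)
    dw <- drop(crossprod(pooled, dlogit))
    db <- sum(dlogit)
    if (model$stochastic$classifier) {
      kw <- kl_to_prior_grad(model$params$head$w, prior)
      kb <- kl_to_prior_grad(model$params$head$b, prior)
      grads$head <- list(
        w = list(mean = dw + pi_i * kw$mean,
                 rho = dw * draw$eps$clf_w * sigmoid(model$params$head$w$rho) +
                   pi_i * kw$rho),
        b = list(mean = db + pi_i * kb$mean,
                 rho = db * draw$eps$clf_b * sigmoid(model$params$head$b$rho) +
                   pi_i * kb$rho))
    } else {
      grads$head <- list(w = dw, b = db)
    }
  } else {
    head <- list(const = model$head_const, params = model$params$head)
    gmu <- -scale * e$dmean
    gvar <- -scale * e$dvar
    hb <- gp_head_backward(head, lat$cache, gmu, gvar, klw = 1 / n_batches)
    grads$head <- hb$grads
    dpooled <- hb$dx
  }

  enc_grads <- encoder_backward(fwd$cache, dpooled)
  if (model$stochastic$embeddings) {
    for (tab in names(enc_grads$emb)) {
      post <- model$params$encoder$emb[[tab]]
      kg <- kl_to_prior_grad(post, prior)
      dtab <- enc_grads$emb[[tab]]
      enc_grads$emb[[tab]] <- list(
        mean = dtab + pi_i * kg$mean,
        rho = dtab * draw$eps[[paste0("emb_", tab)]] * sigmoid(post$rho) +
          pi_i * kg$rho)
    }
  }
  grads$encoder <- enc_grads
  list(loss = loss, grads = grads)
}

#' Training objective for one minibatch
#'
#' Negative of the per-batch evidence lower bound: expected data
#' log-likelihood (GP ELBO data term or Bernoulli log-likelihood of the
#' linear head, scaled to the dataset size), minus the GP KL term spread
#' over the epoch's batches, minus the Blundell-weighted KL of the
#' stochastic weight groups. Uses one fresh weight draw.
#'
#' @param model a `bgpseq_model`.
#' @param records list of `patient_record`s forming the batch.
#' @param n_total dataset size the batch term is scaled to.
#' @param batch_index,n_batches position of this batch within the epoch.
#' @param prior weight prior.
#' @return scalar loss (finite, or an error with diagnostics).
#' @export
training_loss <- function(model, records, n_total = length(records),
                          batch_index = 1L, n_batches = 1L,
                          prior = prior_spec()) {
  model_loss_and_grad(model, records, n_total, batch_index, n_batches,
                      prior, training = FALSE, compute_grad = FALSE)$loss
}

#' Train a model on a cohort
#'
#' Minibatch Adam on the joint objective, one weight draw per step,
#' seeded shuffling; the loss trace records the mean per-datapoint loss
#' of each epoch. Training aborts early if the epoch loss exceeds ten
#' times the initial loss.
#'
#' @param model a `bgpseq_model`.
#' @param records list of `patient_record`s to train on (pass
#'   `cohort$records`, or a pre-split subset).
#' @param config a `training_config`.
#' @return list with the trained `model`, the numeric `trace` of epoch
#'   losses, and the optimizer states.
#' @export
train <- function(model, records, config = training_config()) {
  n <- length(records)
  if (config$epochs == 0L) return(list(model = model, trace = numeric(0)))
  opt_enc <- adam_init(model$params$encoder, lr = config$learning_rate,
                       weight_decay = config$weight_decay)
  opt_head <- adam_init(model$params$head,
                        lr = config$head_learning_rate %||% config$learning_rate,
                        weight_decay = 0,
                        decay_filter = function(p) FALSE)
  trace <- numeric(config$epochs)
  initial_loss <- NA_real_
  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      order_idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      n_batches <- length(starts)
      ep_loss <- 0
      for (bi in seq_along(starts)) {
        idx <- order_idx[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        step_loss <- 0
        for (d in seq_len(config$mc_train_draws)) {
          lg <- model_loss_and_grad(model, records[idx], n, bi, n_batches,
                                    config$prior)
          g <- lg$grads
          if (config$mc_train_draws > 1L) {
            g$encoder <- tree_scale(g$encoder, 1 / config$mc_train_draws)
            g$head <- tree_scale(g$head, 1 / config$mc_train_draws)
          }
          se <- adam_step(opt_enc, model$params$encoder, g$encoder)
          model$params$encoder <- se$params; opt_enc <- se$state
          sh <- adam_step(opt_head, model$params$head, g$head)
          model$params$head <- sh$params; opt_head <- sh$state
          step_loss <- step_loss + lg$loss / config$mc_train_draws
        }
        ep_loss <- ep_loss + step_loss
      }
      trace[ep] <- ep_loss / n
      if (ep == 1L) initial_loss <- trace[1]
      if (trace[ep] > 10 * abs(initial_loss) + 10) {
        warning("training diverged; stopping early")
        trace <- trace[seq_len(ep)]
        break
      }
    }
  })
  list(model = model, trace = trace)
}

#' Seeded train/tune/validation split
#'
#' @param n cohort size; `fractions` must sum to 1.
#' @param seed split seed.
#' @return list of integer index vectors `train`, `tune`, `validation`.
#' @export
split_cohort <- function(n, fractions = c(train = 0.5, tune = 0.2,
                                          validation = 0.3), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  with_seed(derive_seed(seed, "split"), {
    idx <- sample.int(n)
    n_train <- floor(n * fractions[[1]])
    n_tune <- floor(n * fractions[[2]])
    list(train = sort(idx[seq_len(n_train)]),
         tune = sort(idx[n_train + seq_len(n_tune)]),
         validation = sort(idx[(n_train + n_tune + 1L):n]))
  })
}

#' Monte-Carlo predictive distributions
#'
#' Each of the `s` draws fixes one weight sample from every stochastic
#' group and computes each patient's predictive probability (for GP
#' heads, marginalised over the latent with Gauss-Hermite quadrature).
#' Deterministic variants yield `s` identical samples and zero
#' predictive sd.
#'
#' @param model a trained `bgpseq_model`.
#' @param records list of `patient_record`s.
#' @param s number of Monte-Carlo draws (default 30).
#' @param seed sampling seed.
#' @param batch_size forward-pass batch size.
#' @return a `predictive_summary`: list with `probs` (n x s matrix),
#'   `mean_prob`, `std_prob` (sample sd, n-1 denominator), `label`.
#' @export
mc_predict <- function(model, records, s = 30L, seed = 1L, batch_size = 128L) {
  if (s < 1) stop("s must be at least 1")
  n <- length(records)
  labels <- vapply(records, function(r) r$label, integer(1))
  any_stochastic <- model$stochastic$embeddings || model$stochastic$classifier
  one_pass <- function(draw) {
    probs <- numeric(n)
    starts <- seq(1L, n, by = batch_size)
    for (st in starts) {
      idx <- st:min(st + batch_size - 1L, n)
      batch <- pad_batch(records[idx], model$config)
      pooled <- encoder_forward(draw$enc, batch, model$config,
                                training = FALSE)$pooled
      if (model$head_type == "linear") {
        probs[idx] <- sigmoid(bayesian_linear_forward(pooled, draw$head))
      } else {
        head <- list(const = model$head_const, params = model$params$head)
        lat <- predictive_latent(pooled, head)
        probs[idx] <- latent_to_probability(lat$mean, lat$var)
      }
    }
    probs
  }
  probs <- matrix(NA_real_, n, s)
  if (!any_stochastic) {
    p1 <- one_pass(draw_model_weights(model, deterministic = TRUE))
    probs[] <- p1
  } else {
    with_seed(derive_seed(seed, "mc-predict"), {
      for (k in seq_len(s)) probs[, k] <- one_pass(draw_model_weights(model))
    })
  }
  structure(list(probs = probs,
                 mean_prob = rowMeans(probs),
                 std_prob = if (s > 1) apply(probs, 1, stats::sd) else rep(0, n),
                 label = labels),
            class = "predictive_summary")
}

#' Clamp all embedding posterior variances to zero
#'
#' Turns a stochastic-embedding model into its deterministic-limit
#' special case (every draw returns the variational mean), used to check
#' that the hybrid reduces exactly to deep kernel learning.
#' @param model a `bgpseq_model` with stochastic embeddings.
#' @return the modified model.
#' @export
clamp_embedding_variance <- function(model) {
  if (!model$stochastic$embeddings) stop("model has deterministic embeddings")
  for (tab in names(model$params$encoder$emb))
    model$params$encoder$emb[[tab]]$rho[] <- -Inf
  model
}

#' Write / read a predictive summary as CSV
#'
#' Columns: patient_id, label, mean_prob, std_prob, s1..sS.
#' @param summary a `predictive_summary`; `path` file path.
#' @export
write_predictions <- function(summary, path) {
  s <- ncol(summary$probs)
  df <- data.frame(patient_id = seq_along(summary$label),
                   label = summary$label,
                   mean_prob = summary$mean_prob,
                   std_prob = summary$std_prob)
  samples <- as.data.frame(summary$probs)
  names(samples) <- paste0("s", seq_len(s))
  utils::write.csv(cbind(df, samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path)
  need <- c("patient_id", "label", "mean_prob", "std_prob")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("predictions file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  sample_cols <- grep("^s[0-9]+$", names(df), value = TRUE)
  structure(list(probs = as.matrix(df[, sample_cols, drop = FALSE]),
                 mean_prob = df$mean_prob, std_prob = df$std_prob,
                 label = as.integer(df$label)),
            class = "predictive_summary")
}

#' Save / load a model checkpoint
#'
#' Single-archive checkpoint holding the config, variant, every weight
#' tensor and all posterior/GP parameters.
#' @param model a `bgpseq_model`; `path` file path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "bgpseq_model")) stop("not a bgpseq checkpoint")
  model
}

#' Load pretrained deterministic weights as variational means
#'
#' Hook for initialising a stochastic-embedding model from a pretrained
#' deterministic encoder: table means are overwritten, variances kept.
#' @param model stochastic-embedding `bgpseq_model`.
#' @param pretrained deterministic `bgpseq_model` with matching config.
#' @return the updated model.
#' @export
init_from_pretrained <- function(model, pretrained) {
  for (tab in names(model$params$encoder$emb)) {
    src <- pretrained$params$encoder$emb[[tab]]
    if (inherits(src, "mean_field_posterior")) src <- src$mean
    if (inherits(model$params$encoder$emb[[tab]], "mean_field_posterior")) {
      model$params$encoder$emb[[tab]]$mean <- src
    } else {
      model$params$encoder$emb[[tab]] <- src
    }
  }
  for (part in c("emb_ln", "layers", "pool"))
    model$params$encoder[[part]] <- pretrained$params$encoder[[part]]
  model
}
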