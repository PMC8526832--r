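# High-level fitting recipe shared by the pipeline, the tests and the
# acceptance script.
#
# Stochastic-embedding variants (BE, BE+BO, DBGP) are hard to train from
# a cold start at small sample sizes: the weight-KL term inflates the
# embedding noise before the means carry any signal, and single-draw
# gradients are then too noisy to learn from. The remedy mirrors the
# standard warm-start practice for Bayesian networks: first fit a
# deterministic-encoder model, then use
# its weights as the variational means of the stochastic model
# (classifier heads are freshly initialised) and fine-tune.

#' Fit a model variant on a set of records
#'
#' For variants with stochastic embeddings, a deterministic-encoder
#' warm-up model (Bayesian-output architecture) is trained first and its
#' encoder weights become the variational means of the target model; GP
#' and deterministic variants train directly.
#'
#' @param records list of `patient_record`s (training set).
#' @param variant model variant name.
#' @param enc_cfg an `encoder_config`.
#' @param train_cfg a `training_config` for the main fit.
#' @param warm_epochs warm-up epochs (default: same as `train_cfg`;
#'   0 disables the warm start).
#' @param grid_size,n_inducing GP head structure.
#' @param seed initialisation seed (weights; training seed comes from
#'   `train_cfg`).
#' @param warm_model an already-trained deterministic-encoder model to
#'   warm-start from (skips the internal warm-up fit).
#' @return list with the trained `model`, its loss `trace`, the warm-up
#'   trace (`warm_trace`, possibly NULL) and the warm-up model.
#' @export
fit_variant <- function(records, variant, enc_cfg,
                        train_cfg = training_config(),
                        warm_epochs = train_cfg$epochs,
                        grid_size = 32L, n_inducing = 40L, seed = 1L,
                        warm_model = NULL) {
  warm_trace <- NULL
  model <- build_model(variant, enc_cfg, n_inducing = n_inducing,
                       grid_size = grid_size, init_seed = seed)
  if (model$stochastic$embeddings && (warm_epochs > 0 || !is.null(warm_model))) {
    if (is.null(warm_model)) {
      warm <- build_model("BO", enc_cfg, init_seed = seed)
      warm_cfg <- train_cfg
      warm_cfg$epochs <- as.integer(warm_epochs)
      wfit <- train(warm, records, warm_cfg)
      warm_trace <- wfit$trace
      warm_model <- wfit$model
    }
    model <- init_from_pretrained(model, warm_model)
  }
  fit <- train(model, records, train_cfg)
  list(model = fit$model, trace = fit$trace, warm_trace = warm_trace,
       warm_model = warm_model)
}

#' Default desk-scale training configuration
#'
#' Adam settings that converge within a few dozen epochs at cohort sizes
#' of a few thousand (the full-scale default 3e-5 is tuned for
#' million-patient training runs and barely moves at this scale).
#' @param epochs training epochs.
#' @param seed training seed.
#' @export
desk_training_config <- function(epochs = 10L, seed = 1L) {
  training_config(batch_size = 64L, learning_rate = 3e-3,
                  head_learning_rate = 1e-2, epochs = epochs, seed = seed)
}

#' Run the uncertainty-evaluation experiment on one synthetic cohort
#'
#' Generates a cohort, fits the requested variants on the training
#' split (warm-started where stochastic), draws `s` Monte-Carlo
#' predictions on the validation split, and returns the per-variant
#' summaries plus cohort metadata. This is the workhorse behind the
#' package's qualitative uncertainty checks.
#'
#' @param seed experiment seed (cohort, initialisation, training, MC).
#' @param variants character vector of variant names.
#' @param n_patients cohort size; `spec` overrides the whole cohort spec.
#' @param epochs training epochs per stage.
#' @param s Monte-Carlo draws at prediction time.
#' @return list with `summaries` (named by variant), `models`, `cohort`
#'   and the validation indices.
#' @export
uncertainty_experiment <- function(seed = 1L,
                                   variants = c("BE", "DBGP"),
                                   n_patients = 2000L,
                                   epochs = 10L, warm_epochs = 20L,
                                   s = 30L, spec = NULL) {
  if (is.null(spec))
    spec <- cohort_spec(n_patients = n_patients, seed = seed)
  cohort <- generate_cohort(spec)
  enc_cfg <- desk_encoder_config(vocab_size = length(cohort$vocab$tokens))
  idx <- split_cohort(length(cohort$records), seed = seed)
  summaries <- list(); models <- list()
  warm_model <- NULL
  for (v in variants) {
    fit <- fit_variant(cohort$records[idx$train], v, enc_cfg,
                       desk_training_config(epochs = epochs, seed = seed),
                       warm_epochs = warm_epochs, seed = seed,
                       warm_model = warm_model)
    warm_model <- warm_model %||% fit$warm_model
    models[[v]] <- fit$model
    summaries[[v]] <- mc_predict(fit$model, cohort$records[idx$validation],
                                 s = s, seed = derive_seed(seed, paste0("mc-", v)))
  }
  list(summaries = summaries, models = models, cohort = cohort, idx = idx)
}

#' Mean calibration-band width by prediction sign
#'
#' Width of the 95% epistemic band averaged over calibration bins with
#' predicted probability above vs below 0.5, weighted by bin occupancy
#' (so the summary reflects patients, not an arbitrary binning of the
#' probability axis).
#' @param calibration output of [calibration_with_bands()].
#' @return list with `positive`, `negative` mean widths.
#' @export
band_width_by_sign <- function(calibration) {
  width <- calibration$hi - calibration$lo
  mid <- (calibration$bin_lo + calibration$bin_hi) / 2
  ok <- !is.na(width) & calibration$count > 0
  list(positive = stats::weighted.mean(width[ok & mid > 0.5],
                                       calibration$count[ok & mid > 0.5]),
       negative = stats::weighted.mean(width[ok & mid < 0.5],
                                       calibration$count[ok & mid < 0.5]))
}
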