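# Shared fixtures. Trained models are expensive, so the uncertainty
# experiment (cohort -> warm start -> BE/DBGP fits -> MC prediction) is
# cached per seed and reused by the acceptance, training and evaluation
# tests within one suite run.

.fixture_cache <- new.env(parent = emptyenv())

tiny_encoder_config <- function(...) {
  encoder_config(vocab_size = 25L, max_seq_len = 24L, hidden_size = 8L,
                 n_layers = 2L, n_heads = 2L, intermediate_size = 12L,
                 dropout = 0.1, pooled_size = 4L, pos_vocab = 8L, ...)
}

tiny_cohort <- function(n = 40L, seed = 3L, ...) {
  cached(paste0("tiny_cohort_", n, "_", seed), function()
    generate_cohort(cohort_spec(n_patients = n, vocab_size = 20L,
                                n_visits_range = c(2L, 3L),
                                codes_per_visit_range = c(1L, 2L),
                                seed = seed, ...)))
}

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# The study-conditions experiment: n = 2000 patients, 10% positives,
# 2-layer encoder, BE + DBGP, 30 MC draws on the validation split.
get_uncertainty_experiment <- function(seed) {
  cached(paste0("ux_", seed), function()
    uncertainty_experiment(seed = seed, variants = c("BE", "DBGP"),
                           n_patients = 2000L, epochs = 10L,
                           warm_epochs = 20L, s = 30L))
}

# A hand-built predictive summary with known structure.
manual_summary <- function(mean_prob, label, probs = NULL) {
  n <- length(mean_prob)
  if (is.null(probs)) probs <- matrix(mean_prob, n, 2)
  structure(list(probs = probs, mean_prob = mean_prob,
                 std_prob = apply(probs, 1, stats::sd), label = label),
            class = "predictive_summary")
}
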