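# Evaluation suite: ranking metrics, rejection curves, calibration
# bands, the DIV statistic and embedding entropy.

test_that("AUROC and AP match brute-force pair counting and known cases", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.5)
  labels <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auroc(scores, labels), brute_auroc(scores, labels))
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  set.seed(20)
  s <- runif(200); l <- rbinom(200, 1, 0.3)
  expect_equal(auroc(s, l), brute_auroc(s, l), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(auroc(s, l),
                 as.numeric(suppressMessages(pROC::auc(l, s))),
                 tolerance = 1e-10)
  }
  expect_error(auroc(s, rep(1, 200)), "both classes")
})

test_that("label-independent scores give chance-level AUROC at n = 10^4", {
  set.seed(21)
  s <- runif(1e4); l <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(auroc(s, l) - 0.5), 0.02)
})

test_that("bootstrap intervals bracket the point estimates", {
  set.seed(22)
  n <- 400
  l <- rbinom(n, 1, 0.3)
  s <- pmin(pmax(l * 0.4 + runif(n, 0, 0.6), 0), 1)
  summ <- manual_summary(s, l)
  rm <- ranking_metrics(summ, n_bootstrap = 50, seed = 4)
  expect_gte(rm$auroc, rm$auroc_ci[1]); expect_lte(rm$auroc, rm$auroc_ci[2])
  expect_gte(rm$ap, rm$ap_ci[1]); expect_lte(rm$ap, rm$ap_ci[2])
  expect_identical(ranking_metrics(summ, 50, seed = 4)$auroc_ci, rm$auroc_ci)
})

test_that("confidence curves follow the max-class definition on a manual instance", {
  # 8 patients filtered by hand
  p <- c(0.95, 0.9, 0.7, 0.55, 0.45, 0.3, 0.1, 0.5)
  l <- c(1, 1, 0, 1, 0, 0, 0, 1)
  summ <- manual_summary(p, l)
  conf <- pmax(p, 1 - p)
  expect_equal(conf[6], 0.7)      # p = 0.3 has confidence 0.7
  tab <- confidence_curves(summ, thresholds = c(0.5, 0.7, 0.9))
  # tau = 0.5: everyone retained; p == 0.5 is predicted negative (wrong)
  expect_equal(tab$n_retained, c(8L, 5L, 3L))
  pred <- as.integer(p > 0.5)
  expect_equal(tab$accuracy[1], mean(pred == l))
  keep <- conf >= 0.7
  expect_equal(tab$accuracy[2], mean((pred == l)[keep]))
  keep <- conf >= 0.9
  expect_equal(tab$accuracy[3], mean((pred == l)[keep]))
  # all-correct at confidence 0.9: accuracy 1 up to the threshold, empty above
  summ2 <- manual_summary(c(0.9, 0.9, 0.1), c(1, 1, 0))
  tab2 <- confidence_curves(summ2, thresholds = c(0.5, 0.85, 0.95))
  expect_equal(tab2$accuracy[1:2], c(1, 1))
  expect_equal(tab2$n_retained[3], 0L)
  expect_true(is.na(tab2$accuracy[3]))
  expect_error(confidence_curves(summ, thresholds = c(0.4)), "0.5")
})

test_that("calibration bands collapse for deterministic draws and cover the diagonal", {
  # identical MC columns -> zero-width band
  p <- runif(50)
  summ <- manual_summary(p, rbinom(50, 1, p), probs = matrix(p, 50, 5))
  cal <- calibration_with_bands(summ, n_bins = 5)
  expect_equal(cal$lo, cal$hi, tolerance = 1e-12)
  expect_equal(cal$bin_lo[1], 0); expect_equal(cal$bin_hi[5], 1)
  # perfectly calibrated probabilities stay within a binomial envelope
  set.seed(23)
  n <- 4000
  p <- runif(n)
  l <- rbinom(n, 1, p)
  summ <- manual_summary(p, l, probs = cbind(p, p))
  cal <- calibration_with_bands(summ, n_bins = 10)
  mid <- (cal$bin_lo + cal$bin_hi) / 2
  for (j in seq_len(10)) {
    bound <- 3 * sqrt(mid[j] * (1 - mid[j]) / cal$count[j])
    expect_lt(abs(cal$mean_frac[j] - cal$mean_pred[j]), bound + 0.01)
  }
  expect_error(calibration_with_bands(manual_summary(p, l, matrix(p, n, 1))),
               "2 Monte-Carlo")
})

test_that("DIV matches its closed form and quadrature, and is positive iff distinct", {
  split <- structure(list(tp = c(0.2, 0.2, 0.3), fp = c(0.2, 0.2, 0.3),
                          tn = c(0.1, 0.15, 0.2), fn = c(0.3, 0.4, 0.5)),
                     class = "uncertainty_split")
  d <- div_metric(split)
  expect_equal(d$div_positive, 0)
  expect_gt(d$div_negative, 0)
  # closed form: N(0.3, 0.1^2) vs N(0.2, 0.1^2) -> 0.5
  expect_equal(gaussian_kl(0.3, 0.1, 0.2, 0.1), 0.5)
  set.seed(24)
  for (i in 1:20) {
    mu <- rnorm(2); sd <- runif(2, 0.05, 0.5)
    expect_equal(gaussian_kl(mu[1], sd[1], mu[2], sd[2]),
                 quadrature_gaussian_kl(mu[1], sd[1], mu[2], sd[2]),
                 tolerance = 1e-6)
  }
  # degenerate cells are reported, not raised
  degen <- structure(list(tp = 0.1, fp = c(0.2, 0.3), tn = c(0.1, 0.1),
                          fn = c(0.2, 0.25)), class = "uncertainty_split")
  d2 <- div_metric(degen)
  expect_true(is.na(d2$div_positive))
  expect_match(attr(d2$div_positive, "reason"), "fewer than 2")
  expect_true(is.na(div_metric(degen)$div_positive))
})

test_that("uncertainty split partitions the cohort at the 0.5 threshold", {
  summ <- manual_summary(c(0.6, 0.5, 0.4, 0.7), c(1, 1, 0, 0))
  sp <- uncertainty_split(summ)
  expect_equal(length(sp$tp) + length(sp$fp) + length(sp$tn) + length(sp$fn), 4)
  expect_length(sp$tp, 1)   # 0.6 correct positive
  expect_length(sp$fn, 1)   # 0.5 predicted negative despite label 1
  expect_length(sp$fp, 1)   # 0.7 wrong positive
})

test_that("embedding entropy follows its closed forms", {
  expect_equal(gaussian_entropy(1), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-10)
  expect_equal(gaussian_entropy(1), 1.41894, tolerance = 1e-5)
  expect_equal(gaussian_entropy(rep(0.05, 150)),
               150 * (0.5 * log(2 * pi * exp(1)) + log(0.05)),
               tolerance = 1e-8)
  sds <- c(0.1, 0.3, 0.7)
  expect_equal(gaussian_entropy(2 * sds) - gaussian_entropy(sds),
               3 * log(2), tolerance = 1e-10)
})

test_that("the entropy table ranks code tokens ascending and excludes specials", {
  cfg <- tiny_encoder_config()
  model <- build_model("BE", cfg, init_seed = 13)
  vocab <- build_vocabulary(20)
  tab <- embedding_entropy_table(model, vocab)
  expect_equal(nrow(tab), 20)
  expect_false(any(c("PAD", "CLS", "SEP", "MASK", "UNK") %in% tab$token))
  expect_true(!is.unsorted(tab$entropy))
  det <- build_model("KISS_GP", cfg, grid_size = 8, init_seed = 13)
  expect_error(embedding_entropy_table(det, vocab), "undefined")
})

test_that("planted-signal tokens end with lower embedding entropy than noise tokens", {
  hits <- 0L
  for (seed in 1:3) {
    ex <- get_uncertainty_experiment(seed)
    tab <- embedding_entropy_table(ex$models$DBGP, ex$cohort$vocab)
    signal <- tab$entropy[tab$token %in% names(ex$cohort$spec$risk_tokens)]
    noise <- tab$entropy[!tab$token %in% names(ex$cohort$spec$risk_tokens)]
    if (mean(signal) < mean(noise)) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
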