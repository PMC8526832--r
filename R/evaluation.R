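# Uncertainty evaluation: ranking metrics with bootstrap confidence
# intervals, accuracy/AUROC-vs-confidence rejection curves, calibration
# curves with epistemic bands across Monte-Carlo model draws, the DIV
# statistic (KL divergence between Gaussians fitted to the predictive-sd
# distributions of incorrect vs correct predictions), and embedding
# entropy rankings.

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie handling.
#' @param scores numeric scores; `labels` binary 0/1.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Step-wise integral of the precision-recall curve over unique score
#' thresholds (ties grouped).
#' @inheritParams auroc
#' @return AP in (0, 1].
#' @export
average_precision <- function(scores, labels) {
  if (all(labels == 1) || all(labels == 0)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall_step <- diff(c(0, tp)) / sum(labels)
  sum(recall_step * precision)
}

#' Ranking metrics with bootstrap confidence intervals
#'
#' AUROC and average precision of the mean predictive probability, with
#' percentile 95% intervals from seeded patient-level resampling.
#'
#' @param summary a `predictive_summary`.
#' @param n_bootstrap number of bootstrap resamples (default 50).
#' @param seed resampling seed.
#' @return list with `auroc`, `ap`, and `auroc_ci` / `ap_ci` (length-2
#'   percentile bounds).
#' @export
ranking_metrics <- function(summary, n_bootstrap = 50L, seed = 1L) {
  scores <- summary$mean_prob; labels <- summary$label
  if (length(unique(labels)) < 2) stop("both classes must be present")
  point_auroc <- auroc(scores, labels)
  point_ap <- average_precision(scores, labels)
  n <- length(scores)
  boots <- with_seed(derive_seed(seed, "bootstrap"), {
    t(vapply(seq_len(n_bootstrap), function(b) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      c(auroc(scores[idx], labels[idx]),
        average_precision(scores[idx], labels[idx]))
    }, numeric(2)))
  })
  list(auroc = point_auroc, ap = point_ap,
       auroc_ci = unname(stats::quantile(boots[, 1], c(0.025, 0.975))),
       ap_ci = unname(stats::quantile(boots[, 2], c(0.025, 0.975))),
       n_bootstrap = n_bootstrap)
}

#' Accuracy and AUROC as a function of confidence
#'
#' Confidence is `max(p, 1 - p)` of the mean predictive probability;
#' predictions with probability exactly 0.5 count as negative. At each
#' threshold, patients with confidence below it are rejected and
#' accuracy (and AUROC, where both classes survive) is computed on the
#' remainder.
#'
#' @param summary a `predictive_summary`.
#' @param thresholds confidence grid within `[0.5, 1)`.
#' @return data.frame with columns `threshold`, `n_retained`,
#'   `accuracy`, `auroc` (NA where undefined).
#' @export
confidence_curves <- function(summary, thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (any(thresholds < 0.5 | thresholds >= 1))
    stop("thresholds must lie in [0.5, 1)")
  p <- summary$mean_prob
  conf <- pmax(p, 1 - p)
  pred <- as.integer(p > 0.5)
  out <- lapply(thresholds, function(tau) {
    keep <- conf >= tau
    if (!any(keep))
      return(data.frame(threshold = tau, n_retained = 0L,
                        accuracy = NA_real_, auroc = NA_real_))
    acc <- mean(pred[keep] == summary$label[keep])
    auc <- if (length(unique(summary$label[keep])) == 2)
      auroc(p[keep], summary$label[keep]) else NA_real_
    data.frame(threshold = tau, n_retained = sum(keep),
               accuracy = acc, auroc = auc)
  })
  do.call(rbind, out)
}

#' Calibration curves with epistemic bands
#'
#' Each Monte-Carlo weight draw is treated as an independent model: its
#' predicted probabilities are binned into `n_bins` equal-width bins
#' (half-open, last bin closed) and the fraction of positives per bin is
#' recorded. The report gives the per-bin mean curve and the 2.5/97.5
#' percentile band across draws; bins that are empty in every draw keep
#' count 0 and an NA curve.
#'
#' @param summary a `predictive_summary` with at least 2 MC samples.
#' @param n_bins number of probability bins.
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_pred`, `mean_frac`,
#'   `lo`, `hi`, `count` (mean patients per bin across draws).
#' @export
calibration_with_bands <- function(summary, n_bins = 10L) {
  s <- ncol(summary$probs)
  if (s < 2) stop("at least 2 Monte-Carlo samples are required for bands")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin_of <- function(p) pmin(findInterval(p, edges, rightmost.closed = TRUE), n_bins)
  frac <- matrix(NA_real_, n_bins, s)
  pred <- matrix(NA_real_, n_bins, s)
  count <- matrix(0, n_bins, s)
  for (k in seq_len(s)) {
    b <- bin_of(summary$probs[, k])
    for (j in seq_len(n_bins)) {
      in_bin <- b == j
      count[j, k] <- sum(in_bin)
      if (any(in_bin)) {
        frac[j, k] <- mean(summary$label[in_bin])
        pred[j, k] <- mean(summary$probs[in_bin, k])
      }
    }
  }
  data.frame(
    bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
    mean_pred = rowMeans(pred, na.rm = TRUE),
    mean_frac = rowMeans(frac, na.rm = TRUE),
    lo = apply(frac, 1, function(x) if (all(is.na(x))) NA_real_ else
      stats::quantile(x, 0.025, na.rm = TRUE)),
    hi = apply(frac, 1, function(x) if (all(is.na(x))) NA_real_ else
      stats::quantile(x, 0.975, na.rm = TRUE)),
    count = rowMeans(count))
}

#' Split predictive uncertainties by prediction sign and correctness
#'
#' Patients with mean predictive probability above 0.5 are predicted
#' positive (exactly 0.5 counts as negative); each sign is split into
#' correct (TP / TN) and incorrect (FP / FN) cells, carrying the
#' predictive standard deviations.
#'
#' @param summary a `predictive_summary`.
#' @param threshold decision threshold (default 0.5).
#' @return an `uncertainty_split`: list of numeric vectors `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
uncertainty_split <- function(summary, threshold = 0.5) {
  pred <- summary$mean_prob > threshold
  lab <- summary$label == 1
  structure(list(tp = summary$std_prob[pred & lab],
                 fp = summary$std_prob[pred & !lab],
                 tn = summary$std_prob[!pred & !lab],
                 fn = summary$std_prob[!pred & lab]),
            class = "uncertainty_split")
}

#' DIV: divergence between incorrect and correct uncertainty distributions
#'
#' Within each prediction sign, fits a Gaussian (sample mean, sample sd
#' with n-1 denominator) to the predictive sds of the incorrect (F) and
#' correct (T) cells and returns the closed-form `KL(N_F || N_T)`.
#' Larger values mean the model's uncertainty separates its mistakes
#' from its correct calls more cleanly.
#'
#' @param split an `uncertainty_split`.
#' @return list with `div_positive`, `div_negative` (NA with a `reason`
#'   attribute when a cell is degenerate).
#' @export
div_metric <- function(split) {
  one_sign <- function(f, t) {
    if (length(f) < 2 || length(t) < 2)
      return(structure(NA_real_, reason = "cell with fewer than 2 members"))
    sdf <- stats::sd(f); sdt <- stats::sd(t)
    if (sdf == 0 || sdt == 0)
      return(structure(NA_real_, reason = "cell with zero variance"))
    gaussian_kl(mean(f), sdf, mean(t), sdt)
  }
  list(div_positive = one_sign(split$fp, split$tp),
       div_negative = one_sign(split$fn, split$tn))
}

#' Entropy of a diagonal Gaussian embedding row
#' @param sds vector of per-dimension standard deviations.
#' @return `sum_d 0.5 * ln(2 pi e sds_d^2)` in nats.
#' @export
gaussian_entropy <- function(sds) sum(0.5 * log(2 * pi * exp(1) * sds^2))

#' Embedding-uncertainty ranking of code tokens
#'
#' For each non-special code token, sums the differential entropy of its
#' mean-field embedding posterior across embedding dimensions and ranks
#' tokens ascending (lowest entropy first: the most certain
#' associations).
#'
#' @param model a `bgpseq_model` with stochastic embeddings.
#' @param vocab the `vocabulary` used to build the cohort.
#' @return data.frame with `token`, `entropy`, sorted ascending.
#' @export
embedding_entropy_table <- function(model, vocab) {
  emb <- model$params$encoder$emb$code
  if (!inherits(emb, "mean_field_posterior"))
    stop("embedding entropy is undefined for deterministic embeddings")
  sds <- posterior_sd(emb)
  keep <- !(vocab$tokens %in% SPECIAL_TOKENS)
  ent <- vapply(which(keep), function(i) gaussian_entropy(sds[i, ]), numeric(1))
  out <- data.frame(token = vocab$tokens[keep], entropy = ent)
  out[order(out$entropy), , drop = FALSE]
}

#' Assemble a full evaluation report
#'
#' @param summary a `predictive_summary`.
#' @param n_bootstrap bootstrap resamples for ranking metrics.
#' @param n_bins calibration bins.
#' @param thresholds confidence grid.
#' @param seed bootstrap seed.
#' @return an `evaluation_report` list.
#' @export
evaluation_report <- function(summary, n_bootstrap = 50L, n_bins = 10L,
                              thresholds = seq(0.5, 0.95, by = 0.05),
                              seed = 1L) {
  split <- uncertainty_split(summary)
  div <- div_metric(split)
  structure(list(
    ranking = ranking_metrics(summary, n_bootstrap, seed),
    confidence = confidence_curves(summary, thresholds),
    calibration = calibration_with_bands(summary, n_bins),
    div = div,
    mean_std = list(tp = mean(split$tp), fp = mean(split$fp),
                    tn = mean(split$tn), fn = mean(split$fn))),
    class = "evaluation_report")
}

#' Write an evaluation report as JSON (+ curve CSVs alongside)
#' @param report an `evaluation_report`; `path` the JSON file path.
#' @export
write_evaluation_report <- function(report, path) {
  base <- sub("\\.json$", "", path)
  utils::write.csv(report$confidence, paste0(base, "_confidence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calibration, paste0(base, "_calibration.csv"),
                   row.names = FALSE)
  payload <- list(
    auroc = report$ranking$auroc, ap = report$ranking$ap,
    auroc_ci = report$ranking$auroc_ci, ap_ci = report$ranking$ap_ci,
    div_positive = as.numeric(report$div$div_positive),
    div_negative = as.numeric(report$div$div_negative),
    mean_std = report$mean_std)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
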