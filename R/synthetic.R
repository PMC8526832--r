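# Seeded synthetic EHR cohorts: multi-visit sequences of surrogate
# diagnosis/medication codes with per-encounter age, visit-parity segment
# and visit-rank position channels, and a planted token-driven risk
# process on the log-odds scale. The generator is the test bed for the
# whole pipeline; no attempt is made to mimic real ICD-10/BNF statistics.

SPECIAL_TOKENS <- c("PAD", "CLS", "SEP", "MASK", "UNK")

#' Build a code vocabulary
#'
#' Special tokens occupy ids 0..4 (PAD, CLS, SEP, MASK, UNK), followed by
#' `n_codes` surrogate diagnosis/medication codes `C001, C002, ...`.
#' Ids are contiguous from 0 and the token/id mapping is a bijection.
#'
#' @param n_codes number of non-special code tokens.
#' @return a `vocabulary`: list with `tokens` (character) and `index`
#'   (named integer vector, 0-based ids).
#' @export
build_vocabulary <- function(n_codes) {
  stopifnot(n_codes >= 1)
  tokens <- c(SPECIAL_TOKENS, sprintf("C%03d", seq_len(n_codes)))
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(tokens = tokens, index = index), class = "vocabulary")
}

#' Write / read a vocabulary as plain text (one token per line, id = line
#' number - 1)
#' @param vocab a `vocabulary`; `path` file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path)
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary file")
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens) - 1L, tokens)),
            class = "vocabulary")
}

token_id <- function(vocab, token) unname(vocab$index[token])

#' Specification of a synthetic cohort
#'
#' @param n_patients cohort size.
#' @param positive_rate target fraction of positive labels, in (0, 1).
#'   Default 0.10, inside the 8-16 percent range typical of first-incidence
#'   chronic-disease cohorts.
#' @param vocab_size number of non-special code tokens.
#' @param risk_tokens named numeric vector: code token name -> additive
#'   log-odds effect when the token occurs in a patient's history.
#' @param n_visits_range,codes_per_visit_range inclusive integer ranges.
#' @param baseline_log_odds intercept; `NULL` (default) tunes it by
#'   bisection so the expected positive fraction hits `positive_rate`.
#' @param nuisance_noise_sd sd of Gaussian noise added to the log-odds
#'   before drawing labels; makes the Bayes-optimal AUROC less than 1.
#' @param seed integer seed recorded in the cohort metadata.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 2000L,
                        positive_rate = 0.10,
                        vocab_size = 60L,
                        risk_tokens = c(C001 = 4.0, C002 = 3.0, C003 = 2.0),
                        n_visits_range = c(3L, 6L),
                        codes_per_visit_range = c(2L, 4L),
                        baseline_log_odds = NULL,
                        nuisance_noise_sd = 0.5,
                        seed = 1L) {
  if (positive_rate <= 0 || positive_rate >= 1)
    stop("positive_rate must lie strictly inside (0, 1)")
  if (diff(n_visits_range) < 0 || diff(codes_per_visit_range) < 0)
    stop("ranges must be non-empty")
  if (length(risk_tokens) > vocab_size)
    stop("vocabulary too small for the requested risk tokens")
  if (length(risk_tokens) > 0 && is.null(names(risk_tokens)))
    stop("risk_tokens must be a named vector of code tokens")
  structure(list(n_patients = as.integer(n_patients),
                 positive_rate = positive_rate,
                 vocab_size = as.integer(vocab_size),
                 risk_tokens = risk_tokens,
                 n_visits_range = as.integer(n_visits_range),
                 codes_per_visit_range = as.integer(codes_per_visit_range),
                 baseline_log_odds = baseline_log_odds,
                 nuisance_noise_sd = nuisance_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Each patient receives 3-6 visits (configurable) of uniformly sampled
#' codes; ages start uniform in 40-70 years and advance 0-2 years between
#' visits; segments alternate 0/1 per visit; positions equal the visit
#' rank and increment only after a SEP token. Labels are drawn
#' `Bernoulli(sigmoid(baseline + sum of risk-token effects + noise))`; the
#' truth table stores the noiseless per-patient log-odds.
#'
#' @param spec a `cohort_spec`.
#' @return a `cohort`: list with `records` (list of `patient_record`),
#'   `truth` (data.frame patient_id / true_log_odds / label), `vocab`,
#'   and `spec` (with the tuned baseline filled in).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vocab <- build_vocabulary(spec$vocab_size)
  missing_tok <- setdiff(names(spec$risk_tokens), vocab$tokens)
  if (length(missing_tok))
    stop("risk tokens not in vocabulary: ", paste(missing_tok, collapse = ", "))
  code_ids <- token_id(vocab, setdiff(vocab$tokens, SPECIAL_TOKENS))
  risk_ids <- token_id(vocab, names(spec$risk_tokens))
  cls <- token_id(vocab, "CLS"); sep <- token_id(vocab, "SEP")

  with_seed(derive_seed(spec$seed, "cohort"), {
    n <- spec$n_patients
    records <- vector("list", n)
    score <- numeric(n)
    for (i in seq_len(n)) {
      nv <- sample(seq(spec$n_visits_range[1], spec$n_visits_range[2]), 1L)
      age <- sample(40:70, 1L)
      codes <- cls; ages <- age; segs <- 0L; pos <- 0L
      for (v in seq_len(nv)) {
        nc <- sample(seq(spec$codes_per_visit_range[1],
                         spec$codes_per_visit_range[2]), 1L)
        visit_codes <- sample(code_ids, nc, replace = nc > length(code_ids))
        seg <- (v - 1L) %% 2L
        codes <- c(codes, visit_codes, sep)
        ages <- c(ages, rep(age, nc + 1L))
        segs <- c(segs, rep(seg, nc + 1L))
        pos <- c(pos, rep(v - 1L, nc + 1L))
        age <- age + sample(0:2, 1L)
      }
      records[[i]] <- structure(
        list(codes = as.integer(codes), ages = as.integer(ages),
             segments = as.integer(segs), positions = as.integer(pos),
             label = NA_integer_),
        class = "patient_record")
      if (length(risk_ids))
        score[i] <- sum(spec$risk_tokens[risk_ids %in% codes])
    }
    noise <- stats::rnorm(n, 0, spec$nuisance_noise_sd)
    baseline <- spec$baseline_log_odds
    if (is.null(baseline)) {
      target <- spec$positive_rate
      f <- function(b) mean(sigmoid(b + score + noise)) - target
      baseline <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    }
    labels <- as.integer(stats::runif(n) < sigmoid(baseline + score + noise))
    for (i in seq_len(n)) records[[i]]$label <- labels[i]
    spec$baseline_log_odds <- baseline
    structure(list(records = records,
                   truth = data.frame(patient_id = seq_len(n),
                                      true_log_odds = baseline + score,
                                      label = labels),
                   vocab = vocab, spec = spec),
              class = "cohort")
  })
}

#' Validate the structural invariants of a patient record
#'
#' Checks equal sequence lengths, a leading CLS token, non-decreasing
#' ages, and positions that increment only at SEP boundaries.
#' @param record a `patient_record`.
#' @param vocab the cohort `vocabulary`.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_record <- function(record, vocab) {
  len <- length(record$codes)
  if (length(record$ages) != len || length(record$segments) != len ||
      length(record$positions) != len)
    stop("sequence channels differ in length")
  if (record$codes[1] != token_id(vocab, "CLS"))
    stop("record must start with CLS")
  if (any(diff(record$ages) < 0)) stop("ages must be non-decreasing")
  dp <- diff(record$positions)
  if (any(dp < 0)) stop("positions must be non-decreasing")
  jumps <- which(dp > 0)
  if (any(dp > 1)) stop("positions may only increment by one")
  if (length(jumps) &&
      any(record$codes[jumps] != token_id(vocab, "SEP")))
    stop("positions may increment only at SEP boundaries")
  if (!record$label %in% c(0L, 1L)) stop("label must be 0 or 1")
  invisible(TRUE)
}

#' Write / read a cohort as JSON lines
#'
#' Line 1 is a header object carrying the spec, seed and vocabulary;
#' each following line is one patient. The representation is digit-exact,
#' so `read_cohort(write_cohort(x))` reproduces `x` and repeated writes of
#' the same cohort are byte-identical.
#'
#' @param cohort a `cohort`; `path` output file.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  spec <- cohort$spec
  hspec <- unclass(spec)[!vapply(unclass(spec), is.null, TRUE)]
  hspec$risk_tokens <- as.list(spec$risk_tokens)   # keep token names in JSON
  header <- list(format = "bgpseq-cohort", version = 1L,
                 seed = spec$seed,
                 spec = hspec,
                 vocab = cohort$vocab$tokens)
  lines <- character(length(cohort$records) + 1L)
  lines[1] <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    lines[i + 1L] <- jsonlite::toJSON(
      list(codes = r$codes, ages = r$ages, segments = r$segments,
           positions = r$positions, label = r$label,
           true_log_odds = cohort$truth$true_log_odds[i]),
      auto_unbox = TRUE, digits = NA)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty cohort file")
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) stop("malformed header at line 1"))
  if (!identical(header$format, "bgpseq-cohort"))
    stop("not a bgpseq cohort file")
  spec <- header$spec
  spec_obj <- cohort_spec(
    n_patients = spec$n_patients, positive_rate = spec$positive_rate,
    vocab_size = spec$vocab_size,
    risk_tokens = unlist(spec$risk_tokens),
    n_visits_range = spec$n_visits_range,
    codes_per_visit_range = spec$codes_per_visit_range,
    baseline_log_odds = spec$baseline_log_odds,
    nuisance_noise_sd = spec$nuisance_noise_sd, seed = spec$seed)
  vocab <- structure(list(tokens = header$vocab,
                          index = stats::setNames(
                            seq_along(header$vocab) - 1L, header$vocab)),
                     class = "vocabulary")
  n <- length(lines) - 1L
  records <- vector("list", n)
  tlo <- numeric(n); labels <- integer(n)
  for (i in seq_len(n)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i + 1L]),
                    error = function(e)
                      stop(sprintf("parse error at line %d of %s", i + 1L, path)))
    records[[i]] <- structure(
      list(codes = as.integer(obj$codes), ages = as.integer(obj$ages),
           segments = as.integer(obj$segments),
           positions = as.integer(obj$positions),
           label = as.integer(obj$label)),
      class = "patient_record")
    tlo[i] <- obj$true_log_odds
    labels[i] <- as.integer(obj$label)
  }
  structure(list(records = records,
                 truth = data.frame(patient_id = seq_len(n),
                                    true_log_odds = tlo, label = labels),
                 vocab = vocab, spec = spec_obj),
            class = "cohort")
}
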