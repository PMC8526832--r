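# Variant assembly, the joint objective, the training loop and
# Monte-Carlo prediction.

test_that("variants wire up exactly the named stochastic groups", {
  cfg <- tiny_encoder_config()
  m <- build_model("SPARSE_GP", cfg)
  expect_equal(sum(m$report$stochastic), 0)
  expect_equal(m$head_type, "svgp")

  m <- build_model("BE_BO", cfg)
  expect_setequal(m$report$group[m$report$stochastic],
                  c("embeddings", "classifier"))
  expect_equal(m$head_type, "linear")

  m <- build_model("DBGP", cfg, grid_size = 8)
  expect_equal(m$report$group[m$report$stochastic], "embeddings")
  expect_equal(m$head_type, "kiss")

  m <- build_model("BO", cfg)
  expect_equal(m$report$group[m$report$stochastic], "classifier")
})

test_that("zero classifier weights give log-2 loss and prior-matched KL adds nothing", {
  cfg <- tiny_encoder_config()
  cohort <- tiny_cohort(n = 10)
  model <- build_model("BE", cfg, init_seed = 3)
  # posterior == prior for every embedding table -> weight KL is exactly 0
  for (tab in names(model$params$encoder$emb)) {
    model$params$encoder$emb[[tab]]$mean[] <- 0
    model$params$encoder$emb[[tab]]$rho[] <- softplus_inv(0.374)
  }
  model$params$head$w[] <- 0
  model$params$head$b <- 0
  set.seed(1)
  l0 <- training_loss(model, cohort$records, n_total = 10)
  expect_equal(l0, 10 * log(2), tolerance = 1e-10)
  # perturbing the posterior away from the prior increases the loss via KL
  model$params$encoder$emb$code$mean[1, 1] <- 0.5
  set.seed(1)
  expect_gt(training_loss(model, cohort$records, n_total = 10), l0)
})

test_that("joint objective gradients check out on a small model", {
  cfg <- tiny_encoder_config()
  cohort <- tiny_cohort(n = 6)
  for (variant in c("BE_BO", "DBGP")) {
    model <- build_model(variant, cfg, n_inducing = 4, grid_size = 6,
                         init_seed = 2)
    loss_fn <- function(pp) {
      m2 <- model; m2$params <- pp
      set.seed(77)
      bgpseq:::model_loss_and_grad(m2, cohort$records, n_total = 20,
                                   batch_index = 1, n_batches = 3,
                                   compute_grad = FALSE)$loss
    }
    set.seed(77)
    lg <- bgpseq:::model_loss_and_grad(model, cohort$records, n_total = 20,
                                       batch_index = 1, n_batches = 3)
    set.seed(123)
    expect_lt(fd_check_tree(loss_fn, model$params, lg$grads, per_leaf = 2L),
              1e-4)
  }
})

test_that("zero-epoch training returns the model unchanged and seeds reproduce traces", {
  cfg <- tiny_encoder_config()
  cohort <- tiny_cohort(n = 30)
  model <- build_model("BO", cfg, init_seed = 5)
  out <- train(model, cohort$records, training_config(epochs = 0L))
  expect_identical(out$model$params, model$params)

  tc <- training_config(epochs = 2L, learning_rate = 1e-3, seed = 42L,
                        batch_size = 16L)
  t1 <- train(model, cohort$records, tc)
  t2 <- train(model, cohort$records, tc)
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$model$params, t2$model$params)
})

test_that("mean training loss decreases over the first epochs for every variant", {
  cohort <- cached("elbo_cohort", function()
    generate_cohort(cohort_spec(n_patients = 400L, seed = 31L)))
  enc <- desk_encoder_config(vocab_size = length(cohort$vocab$tokens))
  for (variant in MODEL_VARIANTS) {
    for (seed in 1:3) {
      model <- build_model(variant, enc, grid_size = 16, init_seed = seed)
      fit <- train(model, cohort$records,
                   desk_training_config(epochs = 5L, seed = seed))
      expect_lt(fit$trace[5], fit$trace[1],
                label = sprintf("%s seed %d final loss", variant, seed))
    }
  }
})

test_that("a deterministic variant separates a two-token toy cohort", {
  # one token forces the outcome, the other forbids it; a logistic
  # regression on carrier status is the oracle (perfect separation)
  vocab <- build_vocabulary(6)
  make_rec <- function(token, label) {
    structure(list(codes = c(1L, token, 2L), ages = rep(50L, 3),
                   segments = rep(0L, 3), positions = c(0L, 0L, 0L),
                   label = label), class = "patient_record")
  }
  set.seed(33)
  tokens <- sample(c(5L, 6L), 200, replace = TRUE)
  records <- lapply(tokens, function(tk) make_rec(tk, as.integer(tk == 5L)))
  carrier <- as.integer(tokens == 5L)
  oracle <- suppressWarnings(
    stats::glm(y ~ x, data.frame(y = carrier, x = carrier), family = "binomial"))
  expect_equal(mean((stats::fitted(oracle) > 0.5) == carrier), 1)

  enc <- tiny_encoder_config()
  model <- build_model("KISS_GP", enc, grid_size = 8, init_seed = 7)
  fit <- train(model, records,
               training_config(batch_size = 32L, learning_rate = 1e-2,
                               head_learning_rate = 1e-2, epochs = 30L,
                               seed = 7L))
  summ <- mc_predict(fit$model, records, s = 1, seed = 1)
  acc <- mean((summ$mean_prob > 0.5) == carrier)
  expect_gte(acc, 0.95)
})

test_that("predicted risk recovers a single planted token (rank test)", {
  spec <- cohort_spec(n_patients = 2000L, vocab_size = 60L,
                      risk_tokens = c(C001 = 3.0), seed = 51L)
  cohort <- generate_cohort(spec)
  enc <- desk_encoder_config(vocab_size = length(cohort$vocab$tokens))
  model <- build_model("BO", enc, init_seed = 51)
  fit <- train(model, cohort$records[1:1000],
               desk_training_config(epochs = 16L, seed = 51))
  val <- cohort$records[1001:2000]
  summ <- mc_predict(fit$model, val, s = 5, seed = 2)
  carries <- vapply(val, function(r)
    bgpseq:::token_id(cohort$vocab, "C001") %in% r$codes, logical(1))
  p <- stats::wilcox.test(summ$mean_prob[carries], summ$mean_prob[!carries],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("Monte-Carlo summaries are well-formed", {
  cfg <- tiny_encoder_config()
  cohort <- tiny_cohort(n = 20)
  model <- build_model("BE_BO", cfg, init_seed = 6)
  summ <- mc_predict(model, cohort$records, s = 8, seed = 3)
  expect_true(all(summ$probs >= 0 & summ$probs <= 1))
  expect_true(all(summ$std_prob >= 0))
  expect_equal(summ$mean_prob, rowMeans(summ$probs))
  expect_error(mc_predict(model, cohort$records, s = 0), "at least 1")

  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(summ, path)
  back <- read_predictions(path)
  expect_equal(back$mean_prob, summ$mean_prob, tolerance = 1e-12)
  expect_equal(dim(back$probs), dim(summ$probs))
})

test_that("checkpoints round-trip and pretrained means transfer", {
  cfg <- tiny_encoder_config()
  det <- build_model("KISS_GP", cfg, grid_size = 8, init_seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(det, path)
  expect_identical(load_checkpoint(path)$params, det$params)

  stoch <- build_model("DBGP", cfg, grid_size = 8, init_seed = 10)
  stoch <- init_from_pretrained(stoch, det)
  expect_identical(stoch$params$encoder$emb$code$mean,
                   det$params$encoder$emb$code)
  expect_identical(stoch$params$encoder$layers, det$params$encoder$layers)
})
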