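small_training_setup <- function(seed = 21, n = 200, d = 10, k = 2,
                                 survival = "cox") {
  spec <- synthetic_spec(n = n, d = d, k = k, alpha = 0.4,
                         doc_length_range = c(30, 60), survival = survival,
                         censor_frac = 0.25, seed = seed)
  generate_synthetic(spec)
}

fast_config <- function(..., epochs = 50, seed = 21) {
  training_config(..., epochs = epochs, kl_warmup_epochs = round(epochs * 0.8),
                  d_hidden = 16L, batch_size = 64L, seed = seed)
}

test_that("joint loss composes its terms linearly", {
  expect_equal(joint_loss(1.0, 0.5, 2), 2.0)
  expect_equal(joint_loss(3.2, 100, 0), 3.2)
  expect_equal(joint_loss(1, 2, 0.5) - joint_loss(1, 0, 0.5), 1)
})

test_that("training reduces the loss and is bit-reproducible by seed", {
  gen <- small_training_setup()
  # constant KL weight so per-epoch losses are comparable
  cfg <- fast_config(k = 2, alpha = 2, survival = "cox")
  cfg$kl_warmup_epochs <- 0L
  m1 <- train_scholar(gen$corpus, NULL, cfg)
  expect_lt(tail(m1$log$train_loss, 1), m1$log$train_loss[1])

  m2 <- train_scholar(gen$corpus, NULL, cfg)
  expect_identical(m1$params, m2$params)

  cfg2 <- fast_config(k = 2, alpha = 2, survival = "cox", seed = 22)
  m3 <- train_scholar(gen$corpus, NULL, cfg2)
  expect_false(identical(m1$params$H, m3$params$H))
})

test_that("all four joint model variants train and predict curves", {
  for (dec in c("lda", "sage")) for (sv in c("cox", "aft")) {
    gen <- small_training_setup(survival = if (sv == "aft") "aft" else "cox")
    sp <- split_dataset(gen$corpus, 0.25, 0.25, seed = 3)
    cfg <- fast_config(k = 2, alpha = 2, decoder = dec, survival = sv,
                       epochs = 30)
    m <- train_scholar(sp$train, sp$validation, cfg)
    expect_s3_class(m, "scholar_model")
    ps <- predict_survival(m, sp$test)
    expect_s3_class(ps, "prediction_set")
    expect_true(all(ps$S >= 0 & ps$S <= 1))
    W <- predict_topic_weights(m, sp$test)
    expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-9)
    # background coefficient stays pinned
    cf <- if (sv == "cox") m$params$beta else m$params$theta
    expect_identical(cf[2], 0)
  }
})

test_that("the naive two-stage baseline freezes stage-1 topic parameters", {
  gen <- small_training_setup(seed = 31)
  sp <- split_dataset(gen$corpus, 0.25, 0.25, seed = 31)
  cfg <- fast_config(k = 2, alpha = 2, survival = "cox", epochs = 30,
                     seed = 31)
  naive <- fit_two_stage_naive(sp$train, sp$validation, cfg)

  cfg_unsup <- cfg
  cfg_unsup$survival <- "none"; cfg_unsup$lambda_survival <- 0
  unsup <- train_scholar(sp$train, NULL, cfg_unsup)
  expect_identical(naive$params$H, unsup$params$H)
  expect_identical(naive$params$We, unsup$params$We)

  # stage 2 fits Cox coefficients on the frozen weights (background 0)
  expect_identical(naive$params$beta[2], 0)
  expect_false(all(naive$params$beta == 0))
  # and matches an independent Cox fit on the same fixed weights
  skip_if_not_installed("survival")
  W <- unsup$What_train
  cph <- survival::coxph(survival::Surv(sp$train$time, sp$train$event) ~
                           I(W[, 1]), ties = "breslow")
  expect_equal(naive$params$beta[1], unname(coef(cph)), tolerance = 2e-3)
})

test_that("hyperparameter selection maximizes validation ctd with grid-order ties", {
  expect_identical(survtopic:::select_best_index(c(0.5, 0.7, 0.6)), 2L)
  expect_identical(survtopic:::select_best_index(c(0.6, 0.7, 0.7)), 2L)
  expect_identical(survtopic:::select_best_index(0.5), 1L)
  expect_error(select_hyperparameters(list(), NULL, NULL), "empty")

  gen <- small_training_setup(seed = 41)
  sp <- split_dataset(gen$corpus, 0.25, 0.25, seed = 41)
  grid <- list(fast_config(k = 2, alpha = 2, epochs = 15, seed = 41))
  sel <- select_hyperparameters(grid, sp$train, sp$validation)
  expect_identical(sel$best_index, 1L)
  expect_identical(sel$best, grid[[1]])
  expect_length(sel$val_ctd, 1)
})

test_that("models round-trip through a plain-text checkpoint", {
  gen <- small_training_setup(seed = 51)
  sp <- split_dataset(gen$corpus, 0.25, 0.25, seed = 51)
  cfg <- fast_config(k = 2, alpha = 2, survival = "cox", epochs = 20,
                     seed = 51)
  m <- train_scholar(sp$train, sp$validation, cfg)
  dir <- withr::local_tempdir()
  write_scholar_model(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_scholar_model(dir)
  for (nm in names(m$params))
    expect_equal(back$params[[nm]], m$params[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  expect_equal(back$baseline$surv, m$baseline$surv, tolerance = 1e-12)
  expect_identical(back$config$decoder, m$config$decoder)
  # loaded model predicts identically
  p1 <- predict_survival(m, sp$test)
  p2 <- predict_survival(back, sp$test)
  expect_equal(p1$S, p2$S, tolerance = 1e-10)
})

test_that("diverging training fails loudly", {
  gen <- small_training_setup(seed = 61)
  cfg <- fast_config(k = 2, alpha = 2, survival = "cox", epochs = 5,
                     seed = 61)
  cfg$learning_rate <- 1e6
  expect_error(train_scholar(gen$corpus, NULL, cfg),
               "diverged|non-finite|NaN")
})

test_that("the encoder can consume raw counts behind the flag", {
  gen <- small_training_setup(seed = 71)
  cfg <- fast_config(k = 2, alpha = 2, survival = "cox", epochs = 10,
                     seed = 71)
  cfg$encoder_input <- "raw"
  m <- train_scholar(gen$corpus, NULL, cfg)
  W <- predict_topic_weights(m, gen$corpus)
  expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-9)
  cfg$encoder_input <- "normalized"
  m2 <- train_scholar(gen$corpus, NULL, cfg)
  expect_false(identical(m$params$We, m2$params$We))
})
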