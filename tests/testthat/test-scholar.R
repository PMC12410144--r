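test_that("prior constants follow the Dirichlet approximation", {
  p <- prior_constants(5, 2)
  expect_equal(p$sigma0sq, rep(4 / 10, 5))
  expect_equal(p$mu0, rep(0, 5))
  expect_error(prior_constants(1, 1), "2 topics")
  expect_error(prior_constants(3, 0), "alpha")
})

test_that("encoder is deterministic with the documented affine structure", {
  set.seed(2)
  params <- survtopic:::init_params(6, 3, 4, "lda", "none")
  x <- normalize_rows(matrix(rpois(6, 3) + 1, 1))
  p1 <- encode(x, params); p2 <- encode(x, params)
  expect_identical(p1, p2)
  expect_length(drop(p1$mu), 3)
  expect_length(drop(p1$logsig2), 3)

  # zero weights reduce the mean head to its bias
  params0 <- params
  params0$Wmu <- params0$Wmu * 0
  params0$bmu <- c(0.3, -0.2, 1)
  expect_equal(drop(encode(x, params0)$mu), c(0.3, -0.2, 1))
  expect_error(encode(matrix(0.5, 1, 5), params), "dimension")
})

test_that("reparameterized samples live on the simplex with exact limits", {
  post <- list(mu = c(1, 2, -1), logsig2 = rep(-100, 3))  # sigma ~ 0
  w <- sample_topic_weights(post, rnorm(3))
  expect_equal(w, exp(post$mu) / sum(exp(post$mu)), tolerance = 1e-10)

  post2 <- list(mu = rep(0.7, 4), logsig2 = rep(-100, 4))
  expect_equal(sample_topic_weights(post2, rnorm(4)), rep(0.25, 4))

  set.seed(3)
  for (i in 1:10) {
    post3 <- list(mu = rnorm(5), logsig2 = rnorm(5))
    w3 <- sample_topic_weights(post3, rnorm(5))
    expect_equal(sum(w3), 1, tolerance = 1e-12)
    expect_true(all(w3 > 0))
  }
})

test_that("topic-weight estimates average draws reproducibly", {
  post <- list(mu = c(0.5, -0.5), logsig2 = c(-100, -100))
  expect_equal(estimate_topic_weights(post, 7, seed = 1),
               drop(survtopic:::softmax_rows(matrix(post$mu, 1))),
               tolerance = 1e-10)
  post2 <- list(mu = c(0.3, 0.9, -1), logsig2 = c(0.1, -0.4, 0))
  e1 <- estimate_topic_weights(post2, 50, seed = 7)
  e2 <- estimate_topic_weights(post2, 50, seed = 7)
  expect_identical(e1, e2)
  expect_error(estimate_topic_weights(post2, 0), "n_samples")

  # large-sample estimate agrees with an independent Monte-Carlo oracle
  set.seed(99)
  n_mc <- 2e5
  draws <- matrix(rnorm(n_mc * 3), n_mc, 3)
  sd2 <- sqrt(exp(post2$logsig2))
  Wmc <- survtopic:::softmax_rows(sweep(sweep(draws, 2, sd2, "*"), 2,
                                        post2$mu, "+"))
  mc_mean <- colMeans(Wmc)
  mc_se <- apply(Wmc, 2, sd) / sqrt(n_mc)
  est <- estimate_topic_weights(post2, 2e4, seed = 5)
  se_est <- apply(Wmc, 2, sd) / sqrt(2e4)
  expect_true(all(abs(est - mc_mean) < 3 * sqrt(se_est^2 + mc_se^2)))
})

test_that("word distributions follow the LDA and SAGE decoder forms", {
  set.seed(4)
  H <- matrix(rnorm(12), 3, 4)
  lda <- list(kind = "lda", H = H)
  A <- survtopic:::softmax_rows(H)
  expect_equal(word_distribution(c(1, 0, 0), lda), A[1, ])
  W <- c(0.2, 0.5, 0.3)
  expect_equal(word_distribution(W, lda), drop(W %*% A))
  expect_equal(sum(word_distribution(W, lda)), 1, tolerance = 1e-12)

  gam <- rnorm(4)
  sage0 <- list(kind = "sage", H = H * 0, gamma = gam)
  expect_equal(word_distribution(W, sage0), exp(gam) / sum(exp(gam)))
  sage <- list(kind = "sage", H = H, gamma = gam)
  expect_equal(word_distribution(c(0, 1, 0), sage),
               drop(survtopic:::softmax_rows(matrix(gam + H[2, ], 1))))
  expect_error(word_distribution(c(0.5, 0.5), lda), "dimension")
})

test_that("Gaussian KL to the prior is exact and nonnegative", {
  prior <- prior_constants(2, 1)   # sigma0^2 = 0.5
  at_prior <- list(mu = c(0, 0), logsig2 = log(prior$sigma0sq))
  expect_equal(kl_to_prior(at_prior, prior), 0, tolerance = 1e-12)
  expect_equal(kl_to_prior(list(mu = c(1, 0), logsig2 = log(c(0.5, 0.5))),
                           prior), 1, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    pr <- prior_constants(k, runif(1, 0.2, 3))
    post <- list(mu = rnorm(k), logsig2 = rnorm(k))
    expect_gte(kl_to_prior(post, pr), 0)
  }
  expect_error(kl_to_prior(list(mu = 0:1, logsig2 = c(Inf, 0)), prior),
               "positive and finite")
})

test_that("KL closed form matches Monte-Carlo E[log q - log p]", {
  set.seed(12)
  n_mc <- 1e5
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    prior <- prior_constants(k, runif(1, 0.5, 2))
    post <- list(mu = rnorm(k, sd = 0.8), logsig2 = rnorm(k, sd = 0.5))
    sd_q <- sqrt(exp(post$logsig2))
    z <- sweep(sweep(matrix(rnorm(n_mc * k), n_mc, k), 2, sd_q, "*"),
               2, post$mu, "+")
    logq <- rowSums(vapply(1:k, function(g)
      dnorm(z[, g], post$mu[g], sd_q[g], log = TRUE), numeric(n_mc)))
    logp <- rowSums(vapply(1:k, function(g)
      dnorm(z[, g], 0, sqrt(prior$sigma0sq[g]), log = TRUE), numeric(n_mc)))
    diffs <- logq - logp
    se <- sd(diffs) / sqrt(n_mc)
    expect_lt(abs(kl_to_prior(post, prior) - mean(diffs)), 3 * se)
  }
})

test_that("topic loss decomposes into reconstruction and KL", {
  prior <- prior_constants(3, 1)
  xbar <- matrix(0.25, 2, 4)
  zeta <- matrix(0.25, 2, 4)
  posts <- list(mu = matrix(0, 2, 3),
                logsig2 = matrix(log(prior$sigma0sq[1]), 2, 3))
  expect_equal(topic_loss(xbar, zeta, posts, prior), log(4),
               tolerance = 1e-12)

  # SAGE with zero deviation penalty equals the plain objective
  dec <- list(kind = "sage", H = matrix(rnorm(12), 3, 4), gamma = rnorm(4))
  expect_equal(topic_loss(xbar, zeta, posts, prior, dec, 0),
               topic_loss(xbar, zeta, posts, prior))
  expect_equal(topic_loss(xbar, zeta, posts, prior, dec, 0.01),
               log(4) + 0.01 * sum(dec$H^2), tolerance = 1e-12)

  # permutation invariance over subjects
  set.seed(31)
  xb <- normalize_rows(matrix(rpois(20, 2) + 1, 5, 4))
  zt <- normalize_rows(matrix(runif(20), 5, 4))
  po <- list(mu = matrix(rnorm(15), 5, 3),
             logsig2 = matrix(rnorm(15), 5, 3))
  p <- sample(5)
  expect_equal(topic_loss(xb, zt, po, prior),
               topic_loss(xb[p, ], zt[p, ],
                          list(mu = po$mu[p, ], logsig2 = po$logsig2[p, ]),
                          prior), tolerance = 1e-12)
})

test_that("batch gradients match central finite differences for all variants", {
  set.seed(42)
  d <- 5; k <- 3; B <- 6; dh <- 4
  for (dec in c("lda", "sage")) for (sv in c("cox", "aft")) {
    for (use_bn in c(FALSE, TRUE)) {
      cfg <- training_config(k = k, alpha = 1, decoder = dec, survival = sv,
                             lambda_survival = 2, lambda_ranking = 0.5,
                             lambda_small_deviation = 0.01, d_hidden = dh)
      prior <- prior_constants(k, 1)
      params <- survtopic:::init_params(d, k, dh, dec, sv, init_scale = 0.3)
      if (!is.null(params$beta)) params$beta <- c(rnorm(k - 1), 0)
      if (!is.null(params$theta)) params$theta <- c(rnorm(k - 1), 0)
      xb <- normalize_rows(matrix(rpois(B * d, 3) + 1, B, d))
      y <- rexp(B) + 0.2
      delta <- c(1, rbinom(B - 1, 1, 0.7))
      noise <- matrix(rnorm(B * k), B, k)
      bn <- if (use_bn)
        survtopic:::bn_state_init(k, d, dec == "sage") else NULL
      res <- survtopic:::scholar_batch(params, xb, y, delta, noise, prior,
                                       cfg, grad = TRUE, kl_weight = 0.8,
                                       bn_state = bn)
      f <- function(p) survtopic:::scholar_batch(p, xb, y, delta, noise,
                                                 prior, cfg, grad = FALSE,
                                                 kl_weight = 0.8,
                                                 bn_state = bn)$loss
      h <- 1e-5
      for (nm in names(res$grads)) {
        p0 <- params[[nm]]
        idx <- if (length(p0) > 8) sample(seq_along(p0), 8) else seq_along(p0)
        for (i in idx) {
          if (nm %in% c("beta", "theta") && i == k) next
          pp <- params; pp[[nm]][i] <- p0[i] + h; fp <- f(pp)
          pp[[nm]][i] <- p0[i] - h; fm <- f(pp)
          num <- (fp - fm) / (2 * h)
          an <- res$grads[[nm]][i]
          expect_lt(abs(num - an) / max(1e-6, abs(num), abs(an)), 1e-4)
        }
      }
    }
  }
})
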