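# Shared fixtures built in code: small corpora, random survival data and a
# tiny fitted-model stand-in used by interpretation tests.

make_toy_corpus <- function(n = 40, d = 8, seed = 123) {
  set.seed(seed)
  X <- matrix(rpois(n * d, 2), n, d)
  X[rowSums(X) == 0, 1] <- 1
  counts_corpus(X, NULL, time = rexp(n) + 0.1,
                event = rbinom(n, 1, 0.7))
}

random_survival_data <- function(n, seed = 1, tie_frac = 0) {
  set.seed(seed)
  y <- rexp(n) + 0.05
  if (tie_frac > 0) {
    m <- max(1L, floor(n * tie_frac))
    y[sample(n, m)] <- sample(round(y, 1), m, replace = TRUE)
  }
  list(y = y, delta = rbinom(n, 1, 0.6), scores = rnorm(n))
}

# A deterministic hand-built model (no training) with known topics and
# coefficients; enough structure for interpretation and checkpoint tests.
make_stub_model <- function(k = 3, d = 10, survival = "cox", decoder = "lda",
                            seed = 5) {
  set.seed(seed)
  cfg <- training_config(k = k, alpha = 1, decoder = decoder,
                         survival = survival, d_hidden = 6L, seed = seed)
  params <- survtopic:::init_params(d, k, 6L, decoder, survival,
                                    init_scale = 1)
  if (survival == "cox") params$beta <- c(seq(1.5, 0.5,
                                              length.out = k - 1), 0)
  if (survival == "aft") params$theta <- c(seq(-1, -0.2,
                                               length.out = k - 1), 0)
  structure(list(params = params, config = cfg,
                 prior = prior_constants(k, 1),
                 best_val_ctd = NA_real_),
            class = "scholar_model")
}

# Exhaustive O(n^2) oracle for the time-dependent concordance index,
# independent of the package implementation (direct pair enumeration over
# survival-curve evaluations).
ctd_oracle <- function(curves, y, delta) {
  n <- length(y)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (delta[i] != 1) next
    si <- survival_at(curves[[i]], y[i])
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- y[j] > y[i] || (y[j] == y[i] && delta[j] == 0)
      if (!comparable) next
      sj <- survival_at(curves[[j]], y[i])
      den <- den + 1
      if (si < sj) num <- num + 1
      else if (si == sj) num <- num + 0.5
    }
  }
  list(value = num / den, pairs = den)
}
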