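test_that("linear scores pin the background coefficient at zero", {
  W <- c(0.5, 0.25, 0.25)
  expect_equal(linear_score(W, list(beta = c(1, -1, 99))), 0.25)
  expect_equal(linear_score(c(0, 0, 1), list(beta = c(5, 5, 5))), 0)
  expect_equal(linear_score(W, list(beta = c(0, 0, 0))), 0)
  expect_equal(linear_score(W, list(theta = c(2, 0, 0), mu_aft = 1)), 2)
  expect_error(linear_score(c(0.5, 0.5), list(beta = c(1, 1, 1))),
               "mismatch")
})

test_that("Cox partial-likelihood loss matches hand values and O(n^2) oracle", {
  expect_equal(cox_partial_likelihood_loss(0, 1, 1), 0)
  expect_equal(cox_partial_likelihood_loss(c(0, 0), c(1, 2), c(1, 1)),
               log(2) / 2, tolerance = 1e-12)
  expect_warning(l0 <- cox_partial_likelihood_loss(rnorm(4), 1:4,
                                                   rep(0, 4)), "no uncensored")
  expect_equal(l0, 0)

  # direct double-loop evaluation of the partial likelihood
  cox_oracle <- function(s, y, d) {
    tot <- 0
    for (i in seq_along(s)) if (d[i] == 1)
      tot <- tot + (s[i] - log(sum(exp(s[y >= y[i]]))))
    -tot / length(s)
  }
  for (seed in 1:20) {
    dat <- random_survival_data(30, seed, tie_frac = if (seed %% 2) 0.3 else 0)
    if (sum(dat$delta) == 0) dat$delta[1] <- 1
    expect_equal(cox_partial_likelihood_loss(dat$scores, dat$y, dat$delta),
                 cox_oracle(dat$scores, dat$y, dat$delta),
                 tolerance = 1e-10)
    # shift invariance is exact
    expect_equal(cox_partial_likelihood_loss(dat$scores + 13.7, dat$y,
                                             dat$delta),
                 cox_partial_likelihood_loss(dat$scores, dat$y, dat$delta),
                 tolerance = 1e-10)
  }
})

test_that("Cox loss gradient matches central finite differences", {
  dat <- random_survival_data(15, 3)
  dat$delta[1:5] <- 1
  g <- survtopic:::cox_loss_with_grad(dat$scores, dat$y, dat$delta)$grad
  h <- 1e-6
  for (j in seq_along(dat$scores)) {
    sp <- dat$scores; sp[j] <- sp[j] + h
    sm <- dat$scores; sm[j] <- sm[j] - h
    num <- (cox_partial_likelihood_loss(sp, dat$y, dat$delta) -
              cox_partial_likelihood_loss(sm, dat$y, dat$delta)) / (2 * h)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
})

test_that("Breslow baseline matches hand values and Nelson-Aalen at equal scores", {
  b <- breslow_baseline(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_equal(b$hazards, c(1 / 3, 1 / 2, 1))
  expect_equal(b$surv[3], exp(-11 / 6), tolerance = 1e-12)
  expect_true(all(diff(b$surv) <= 0))

  expect_warning(b0 <- breslow_baseline(rnorm(3), 1:3, c(0, 0, 0)),
                 "no deaths")
  expect_equal(survival_at(cox_survival_curve(0.3, b0), c(0, 5)), c(1, 1))

  # equal scores: cumulative Breslow hazard equals Nelson-Aalen
  skip_if_not_installed("survival")
  dat <- random_survival_data(60, 7, tie_frac = 0.2)
  dat$delta[1:10] <- 1
  b <- breslow_baseline(rep(0, 60), dat$y, dat$delta)
  sf <- survival::survfit(survival::Surv(dat$y, dat$delta) ~ 1,
                          stype = 2, ctype = 1)   # exp(-Nelson-Aalen)
  at_deaths <- summary(sf, times = b$death_times)$surv
  expect_equal(b$surv, at_deaths, tolerance = 1e-10)
})

test_that("Cox survival curves are powers of the baseline and ordered by score", {
  b <- breslow_baseline(c(0.5, -0.5, 0), c(1, 2, 3), c(1, 1, 1))
  c0 <- cox_survival_curve(0, b)
  expect_equal(survival_at(c0, b$death_times), b$surv)
  expect_equal(survival_at(cox_survival_curve(log(2),
                                              list(death_times = 1,
                                                   hazards = log(2),
                                                   surv = 0.5)), 1), 0.25)
  ca <- cox_survival_curve(-1, b); cb <- cox_survival_curve(1, b)
  tt <- seq(0, 4, by = 0.25)
  expect_true(all(survival_at(ca, tt) >= survival_at(cb, tt)))
})

test_that("AFT likelihood matches hand values and the log-logistic density", {
  expect_equal(aft_nll(0, 0, 1, 1), log(4), tolerance = 1e-12)   # z = 0 event
  expect_equal(aft_nll(0, 0, 1, 0), log(2), tolerance = 1e-12)   # z = 0 censored
  # deeply censored subject contributes ~ nothing
  expect_lt(aft_nll(20, 0, 1, 0), 1e-8)
  expect_error(aft_nll(0, 0, -1, 1), "positive")

  # density implied by the NLL equals -dS/dt by central differences
  loc <- 0.7; sig <- 0.4
  for (t in c(0.5, 1, 2.5)) {
    f_nll <- exp(-aft_nll(loc, log(sig), t, 1)) / t   # f(t) = f_eps(z)/(sigma t)
    h <- 1e-5
    f_num <- -(loglogistic_survival(loc, sig, t + h) -
                 loglogistic_survival(loc, sig, t - h)) / (2 * h)
    expect_equal(f_nll, f_num, tolerance = 1e-6)
  }
})

test_that("AFT gradients match finite differences", {
  dat <- random_survival_data(12, 5)
  y <- abs(dat$y) + 0.1
  loc <- rnorm(12); ls <- 0.3
  g <- survtopic:::aft_nll_with_grad(loc, ls, y, dat$delta)
  h <- 1e-6
  for (j in 1:12) {
    lp <- loc; lp[j] <- lp[j] + h
    lm <- loc; lm[j] <- lm[j] - h
    expect_equal(g$dloc[j],
                 (aft_nll(lp, ls, y, dat$delta) -
                    aft_nll(lm, ls, y, dat$delta)) / (2 * h),
                 tolerance = 1e-4)
  }
  expect_equal(g$dlogsig,
               (aft_nll(loc, ls + h, y, dat$delta) -
                  aft_nll(loc, ls - h, y, dat$delta)) / (2 * h),
               tolerance = 1e-4)
})

test_that("ranking loss has the stated values, limits and monotonicity", {
  expect_equal(ranking_loss(rep(1.3, 5), 1:5, rep(1, 5)), 0)
  # single comparable pair with location gap log 3 (earlier death higher)
  expect_equal(ranking_loss(c(log(3), 0), c(1, 2), c(1, 0)), 1,
               tolerance = 1e-12)
  expect_equal(ranking_loss(rnorm(4), 1:4, rep(0, 4)), 0)  # no pairs

  # widening a concordant gap lowers the loss
  l1 <- ranking_loss(c(-1, 1), c(1, 2), c(1, 1))
  l2 <- ranking_loss(c(-2, 2), c(1, 2), c(1, 1))
  expect_lt(l2, l1)

  # gradient check
  dat <- random_survival_data(10, 9)
  dat$delta[1:4] <- 1
  loc <- rnorm(10)
  g <- survtopic:::ranking_loss_with_grad(loc, dat$y, dat$delta)$grad
  h <- 1e-6
  for (j in 1:10) {
    lp <- loc; lp[j] <- lp[j] + h
    lm <- loc; lm[j] <- lm[j] - h
    expect_equal(g[j], (ranking_loss(lp, dat$y, dat$delta) -
                          ranking_loss(lm, dat$y, dat$delta)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("log-logistic survival has closed-form properties", {
  expect_equal(loglogistic_survival(1.2, 0.5, 0), 1)
  expect_equal(loglogistic_survival(1.2, 0.5, exp(1.2)), 0.5)  # median
  tt <- seq(0.1, 10, by = 0.1)
  expect_true(all(diff(loglogistic_survival(0.3, 0.7, tt)) < 0))
  expect_error(loglogistic_survival(0, -1, 1), "sigma")
})

test_that("survival curves export to CSV on a user grid", {
  b <- breslow_baseline(c(0, 0.5), c(1, 2), c(1, 1))
  curves <- list(cox_survival_curve(0, b), cox_survival_curve(1, b))
  f <- withr::local_tempfile(fileext = ".csv")
  grid <- c(0, 0.5, 1, 1.5, 2, 3)
  out <- export_survival_curves(curves, grid, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$time, grid)
  expect_equal(back[["1"]], survival_at(curves[[1]], grid))
  expect_equal(back[["2"]], survival_at(curves[[2]], grid))
})
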