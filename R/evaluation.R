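#' Bundle survival-curve predictions with their labels
#'
#' Precomputes every curve on the grid of observed label times so that the
#' concordance index and its bootstrap replicates reduce to fast matrix
#' lookups. Step curves are evaluated right-continuously.
#'
#' @param curves list of \code{survival_curve} objects, one per subject.
#' @param time observed times; @param event event indicators.
#' @param subject_ids optional identifiers (used to check alignment between
#'   prediction sets in paired bootstraps).
#' @return object of class \code{prediction_set}.
#' @export
prediction_set <- function(curves, time, event, subject_ids = NULL) {
  n <- length(curves)
  stopifnot(length(time) == n, length(event) == n)
  if (is.null(subject_ids)) subject_ids <- seq_len(n)
  grid <- sort(unique(time))
  S <- t(vapply(curves, function(cv) survival_at(cv, grid),
                numeric(length(grid))))   # n x m: S[j, t] = S_j(grid[t])
  if (any(S > 1 + 1e-9) | any(S < -1e-9))
    stop("survival curves must take values in [0, 1]", call. = FALSE)
  bad <- apply(S, 1L, function(r) any(diff(r) > 1e-9))
  if (any(bad))
    stop("survival curves must be nonincreasing", call. = FALSE)
  structure(list(S = S, grid = grid, time = time, event = as.integer(event),
                 subject_ids = subject_ids),
            class = "prediction_set")
}

#' Time-dependent concordance index
#'
#' Antolini's \eqn{C^{td}}: over comparable pairs \eqn{(i, j)} — subject i
#' has an observed event at \eqn{Y_i} and either \eqn{Y_j > Y_i}, or
#' \eqn{Y_j = Y_i} with j censored — a pair is concordant when the curves
#' evaluated at the earlier subject's event time order the pair correctly,
#' \eqn{\hat S(Y_i \mid i) < \hat S(Y_i \mid j)}. Tied predictions get
#' credit 1/2. Returns concordant mass over comparable pairs, in [0, 1].
#'
#' @param preds a \code{prediction_set}.
#' @param idx optional subject indices (with repeats) defining a bootstrap
#'   resample; default uses all subjects once.
#' @return scalar concordance in [0, 1].
#' @export
ctd_index <- function(preds, idx = NULL) {
  out <- ctd_index_impl(preds, idx)
  if (out$pairs == 0)
    stop("no comparable pairs; Ctd is undefined", call. = FALSE)
  out$value
}

ctd_index_impl <- function(preds, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(preds$time)
  y <- preds$time[idx]; d <- preds$event[idx]
  pos <- match(y, preds$grid)
  SY <- preds$S[idx, pos, drop = FALSE]    # SY[j, i] = S_j(Y_i)
  n <- length(idx)
  own <- SY[cbind(seq_len(n), seq_len(n))] # S_i(Y_i)
  comp <- (d == 1) & (outer(y, y, "<") | (outer(y, y, "==") &
                                            outer(rep(TRUE, n), d == 0, "&")))
  diag(comp) <- FALSE
  other <- t(SY)                           # other[i, j] = S_j(Y_i)
  conc <- other > own
  tie <- other == own
  num <- sum(conc[comp]) + 0.5 * sum(tie[comp])
  den <- sum(comp)
  list(value = if (den > 0) num / den else NA_real_, pairs = den)
}

#' Bootstrap percentile confidence interval for Ctd
#'
#' Resamples subjects with replacement \code{B} times, recomputes the
#' concordance per replicate, and returns the nearest-rank 2.5 and 97.5
#' empirical percentiles. Replicates with no comparable pair are skipped and
#' counted.
#'
#' @param preds a \code{prediction_set}; @param B number of replicates
#'   (default 1000); @param seed RNG seed.
#' @param probs lower/upper percentile levels (default \code{c(.025, .975)}).
#' @return list with \code{lower}, \code{upper}, \code{replicates},
#'   \code{n_skipped}.
#' @export
bootstrap_ci <- function(preds, B = 1000L, seed = 1L,
                         probs = c(0.025, 0.975)) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  n <- length(preds$time)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ctd_index_impl(preds, idx)$value
    }, numeric(1))
  })
  keep <- reps[!is.na(reps)]
  ci <- nearest_rank_percentile(keep, probs)
  list(lower = ci[1], upper = ci[2], replicates = keep,
       n_skipped = sum(is.na(reps)))
}

#' Bootstrap percentile interval for a paired Ctd difference
#'
#' For two prediction sets over the same subjects, draws one resample per
#' replicate, computes \code{ctd(A) - ctd(B)} on that common resample, and
#' returns the nearest-rank percentile interval of the differences.
#'
#' @param predsA,predsB \code{prediction_set}s aligned on the same subjects.
#' @inheritParams bootstrap_ci
#' @return list with \code{lower}, \code{upper}, \code{replicates},
#'   \code{n_skipped}.
#' @export
bootstrap_diff_ci <- function(predsA, predsB, B = 1000L, seed = 1L,
                              probs = c(0.025, 0.975)) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!identical(predsA$subject_ids, predsB$subject_ids) ||
      !identical(predsA$time, predsB$time) ||
      !identical(predsA$event, predsB$event))
    stop("prediction sets are not aligned on the same subjects",
         call. = FALSE)
  n <- length(predsA$time)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ctd_index_impl(predsA, idx)$value - ctd_index_impl(predsB, idx)$value
    }, numeric(1))
  })
  keep <- reps[!is.na(reps)]
  ci <- nearest_rank_percentile(keep, probs)
  list(lower = ci[1], upper = ci[2], replicates = keep,
       n_skipped = sum(is.na(reps)))
}

# Nearest-rank empirical percentile: value at rank ceiling(p * n) of the
# sorted sample (deterministic across platforms; no interpolation).
nearest_rank_percentile <- function(x, probs) {
  s <- sort(x)
  n <- length(s)
  s[pmin(pmax(ceiling(probs * n), 1L), n)]
}
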