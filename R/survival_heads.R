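#' Linear survival score of a topic-weight vector
#'
#' Cox head: \eqn{\beta^\top W} with the background coefficient
#' \eqn{\beta_k = 0}; larger scores mean pointwise lower survival curves.
#' AFT head: the location \eqn{\theta^\top W + \mu} of log survival time,
#' with \eqn{\theta_k = 0}; larger locations mean longer survival.
#'
#' @param W topic-weight vector or n x k matrix.
#' @param head list with either \code{beta}, or \code{theta} and
#'   \code{mu_aft}. The k-th coefficient is forced to zero.
#' @return numeric score(s).
#' @export
linear_score <- function(W, head) {
  vec <- is.null(dim(W))
  if (vec) W <- matrix(W, 1)
  if (!is.null(head$beta)) {
    b <- head$beta; b[length(b)] <- 0
    if (ncol(W) != length(b)) stop("dimension mismatch", call. = FALSE)
    s <- drop(W %*% b)
  } else {
    th <- head$theta; th[length(th)] <- 0
    if (ncol(W) != length(th)) stop("dimension mismatch", call. = FALSE)
    s <- drop(W %*% th) + (head$mu_aft %||% 0)
  }
  s
}

#' Negative Cox partial log-likelihood (Breslow risk sets)
#'
#' \deqn{-\frac1n \sum_{i:\delta_i=1} \left[ s_i - \log \sum_{j: Y_j \ge
#'   Y_i} e^{s_j} \right],}
#' where the risk set at an event time includes every subject with
#' \eqn{Y_j \ge Y_i} (ties stay in the risk set). Invariant to adding a
#' constant to all scores. With no observed events the loss is 0 (with a
#' warning).
#'
#' @param scores n linear predictors.
#' @param y observed times; @param delta event indicators in \{0,1\}.
#' @return scalar loss.
#' @export
cox_partial_likelihood_loss <- function(scores, y, delta) {
  cox_loss_with_grad(scores, y, delta, grad = FALSE)$loss
}

# loss + gradient wrt scores, O(n^2) risk-set matrix
cox_loss_with_grad <- function(scores, y, delta, grad = TRUE) {
  n <- length(scores)
  stopifnot(length(y) == n, length(delta) == n)
  if (sum(delta) == 0) {
    warning("no uncensored subjects; Cox loss is 0")
    return(list(loss = 0, grad = rep(0, n)))
  }
  sc <- scores - max(scores)               # shift invariance, overflow guard
  es <- exp(sc)
  R <- outer(y, y, FUN = "<=")             # R[i, j] = 1{Y_j >= Y_i}
  risk <- drop(R %*% es)                   # risk-set sums at each i
  ev <- delta == 1
  loss <- -mean(ifelse(ev, sc - log(risk), 0))
  if (!grad) return(list(loss = loss))
  # d/ds_j: -(1/n) [delta_j - e^{s_j} sum_{i: ev, Y_j >= Y_i} 1/risk_i]
  w <- ifelse(ev, 1 / risk, 0)
  g <- -(as.numeric(ev) - es * drop(crossprod(R, w))) / n
  list(loss = loss, grad = g)
}

#' Breslow baseline survival estimator
#'
#' At each unique event time \eqn{t_i} with \eqn{d_i} deaths, the hazard
#' increment is \eqn{\hat h_i = d_i / \sum_{j: Y_j \ge t_i} e^{s_j}}; the
#' baseline survival is \eqn{\hat S_0(t) = \exp(-\sum_{t_i \le t} \hat
#' h_i)}, a right-continuous nonincreasing step function with
#' \eqn{\hat S_0(t) = 1} before the first event time.
#'
#' @param scores n fitted linear predictors.
#' @param y observed times; @param delta event indicators.
#' @return object of class \code{baseline_survival} with \code{death_times},
#'   \code{hazards}, \code{surv} (step values at the death times).
#' @export
breslow_baseline <- function(scores, y, delta) {
  if (sum(delta) == 0) {
    warning("no deaths observed; baseline survival is identically 1")
    return(structure(list(death_times = numeric(0), hazards = numeric(0),
                          surv = numeric(0)), class = "baseline_survival"))
  }
  es <- exp(scores - max(scores))
  scale <- exp(max(scores))                 # undo the shift in the risk sums
  dt <- sort(unique(y[delta == 1]))
  dcount <- vapply(dt, function(t) sum(delta == 1 & y == t), numeric(1))
  risk <- vapply(dt, function(t) sum(es[y >= t]) * scale, numeric(1))
  h <- dcount / risk
  structure(list(death_times = dt, hazards = h, surv = exp(-cumsum(h))),
            class = "baseline_survival")
}

#' Subject-specific Cox survival curve
#'
#' \eqn{\hat S(t \mid w) = \hat S_0(t)^{\exp(s)}} for linear score
#' \eqn{s = \beta^\top w}; larger scores give pointwise lower curves.
#'
#' @param score linear predictor.
#' @param baseline a \code{baseline_survival}.
#' @return a step \code{survival_curve}.
#' @export
cox_survival_curve <- function(score, baseline) {
  survival_curve_step(baseline$death_times, baseline$surv ^ exp(score))
}

#' Step survival curve
#' @param time increasing jump times; @param surv survival values just after
#'   each jump (right-continuous). \eqn{S(t) = 1} before the first jump.
#' @return object of class \code{survival_curve}.
#' @export
survival_curve_step <- function(time, surv) {
  stopifnot(length(time) == length(surv), !is.unsorted(time))
  structure(list(kind = "step", time = time, surv = surv),
            class = "survival_curve")
}

#' Log-logistic survival curve
#' @param location location of log survival time; @param sigma scale (> 0).
#' @return object of class \code{survival_curve}.
#' @export
survival_curve_loglogistic <- function(location, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(kind = "loglogistic", location = location, sigma = sigma),
            class = "survival_curve")
}

#' Evaluate a survival curve
#' @param curve a \code{survival_curve}; @param t vector of times (>= 0).
#' @return survival probabilities \eqn{S(t)}.
#' @export
survival_at <- function(curve, t) {
  if (curve$kind == "step") {
    idx <- findInterval(t, curve$time)
    c(1, curve$surv)[idx + 1L]
  } else {
    loglogistic_survival(curve$location, curve$sigma, t)
  }
}

#' @export
print.survival_curve <- function(x, ...) {
  if (x$kind == "step")
    cat(sprintf("step survival curve with %d jump times\n", length(x$time)))
  else
    cat(sprintf("log-logistic survival curve (location %.3f, scale %.3f)\n",
                x$location, x$sigma))
  invisible(x)
}

#' Export survival curves to CSV on a time grid
#'
#' Writes one row per grid time with one column per curve (plus the
#' \code{time} column), evaluating each curve right-continuously.
#'
#' @param curves list of \code{survival_curve}s (or a \code{prediction_set},
#'   whose grid-evaluated matrix is reused).
#' @param times numeric evaluation grid.
#' @param file output CSV path.
#' @param ids optional column names, one per curve.
#' @return the written data frame, invisibly.
#' @export
export_survival_curves <- function(curves, times, file, ids = NULL) {
  if (inherits(curves, "prediction_set")) {
    ids <- ids %||% curves$subject_ids
    S <- t(vapply(seq_len(nrow(curves$S)), function(j) {
      c(1, curves$S[j, ])[findInterval(times, curves$grid) + 1L]
    }, numeric(length(times))))
  } else {
    S <- t(vapply(curves, function(cv) survival_at(cv, times),
                  numeric(length(times))))
    ids <- ids %||% seq_along(curves)
  }
  out <- data.frame(time = times, t(S))
  names(out) <- c("time", as.character(ids))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Log-logistic survival function
#'
#' \deqn{S(t) = \frac{1}{1 + t^{1/\sigma} e^{-\mathrm{location}/\sigma}},}
#' the closed-form survival function when log event time is
#' location + \eqn{\sigma \epsilon} with standard-logistic noise. The median
#' survival time is \eqn{e^{\mathrm{location}}}.
#'
#' @param location location parameter; @param sigma scale (> 0);
#' @param t times (>= 0).
#' @return survival probabilities.
#' @export
loglogistic_survival <- function(location, sigma, t) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  1 / (1 + exp((log(pmax(t, 0)) - location) / sigma) * (t > 0))
}

#' Log-logistic AFT negative log-likelihood
#'
#' With \eqn{z_i = (\log Y_i - \mathrm{loc}_i)/\sigma}, standard-logistic
#' density \eqn{f_\epsilon} and CDF \eqn{F_\epsilon}:
#' \deqn{-\frac1n \sum_i \left[ \delta_i \log f_\epsilon(z_i) - \delta_i
#'   \log\sigma + (1-\delta_i)\log(1 - F_\epsilon(z_i)) \right].}
#' Event subjects contribute the log-density of their observed time;
#' censored subjects contribute the log survival probability beyond their
#' censoring time.
#'
#' @param locations n location parameters (one per subject).
#' @param log_sigma log of the common scale.
#' @param y observed times (> 0); @param delta event indicators.
#' @return scalar loss.
#' @export
aft_nll <- function(locations, log_sigma, y, delta) {
  aft_nll_with_grad(locations, log_sigma, y, delta, grad = FALSE)$loss
}

aft_nll_with_grad <- function(locations, log_sigma, y, delta, grad = TRUE) {
  n <- length(y)
  stopifnot(length(locations) == n, length(delta) == n)
  if (any(y <= 0)) stop("AFT requires strictly positive times", call. = FALSE)
  sig <- exp(log_sigma)
  z <- (log(y) - locations) / sig
  # log f(z) = z - 2 log(1 + e^z); log (1 - F(z)) = -log(1 + e^z)
  log1pez <- softplus(z)
  logf <- z - 2 * log1pez
  logS <- -log1pez
  loss <- -mean(delta * (logf - log_sigma) + (1 - delta) * logS)
  if (!grad) return(list(loss = loss))
  Fz <- stats::plogis(z)
  dz <- -(delta * (1 - 2 * Fz) - (1 - delta) * Fz) / n
  dloc <- dz * (-1 / sig)
  dlogsig <- sum(dz * (-z)) + sum(delta) / n
  list(loss = loss, dloc = dloc, dlogsig = dlogsig, z = z)
}

#' Concordance-based ranking loss
#'
#' Over comparable pairs \eqn{\mathcal{E} = \{(i,j): \delta_i = 1,\;
#' Y_j > Y_i\}}:
#' \deqn{-1 + \frac{1}{|\mathcal{E}|} \sum_{(i,j)}
#'   \log_2\!\left(1 + e^{\,\mathrm{loc}_i - \mathrm{loc}_j}\right).}
#' Its negation lower-bounds a concordance index, so minimizing it pushes
#' subjects with longer observed survival toward larger locations. Returns 0
#' when no comparable pair exists.
#'
#' @param locations n linear AFT scores (intercept excluded; it cancels).
#' @param y observed times; @param delta event indicators.
#' @return scalar loss.
#' @export
ranking_loss <- function(locations, y, delta) {
  ranking_loss_with_grad(locations, y, delta, grad = FALSE)$loss
}

ranking_loss_with_grad <- function(locations, y, delta, grad = TRUE) {
  n <- length(y)
  P <- outer(delta == 1, rep(TRUE, n), "&") & outer(y, y, "<")  # pairs (i, j)
  m <- sum(P)
  if (m == 0) return(list(loss = 0, grad = rep(0, n)))
  U <- outer(locations, locations, "-")
  loss <- -1 + sum(softplus(U[P])) / (m * log(2))
  if (!grad) return(list(loss = loss))
  Q <- matrix(0, n, n)
  Q[P] <- stats::plogis(U[P]) / (m * log(2))
  list(loss = loss, grad = rowSums(Q) - colSums(Q))
}
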