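#' Logistic-normal prior constants approximating a symmetric Dirichlet
#'
#' The amortized-variational topic model places a diagonal Gaussian prior
#' \eqn{N(\mu_0, \mathrm{diag}\,\sigma_0^2)} on the unnormalized topic
#' weights, with \eqn{\mu_0 = 0} and every entry of \eqn{\sigma_0^2} equal to
#' \eqn{(k-1)/(\alpha k)}: the Laplace-type approximation of a symmetric
#' Dirichlet with concentration \eqn{\alpha} after the softmax map.
#'
#' @param k number of topics (>= 2).
#' @param alpha Dirichlet concentration (> 0).
#' @return list with \code{k}, \code{alpha}, \code{mu0}, \code{sigma0sq}.
#' @export
prior_constants <- function(k, alpha) {
  if (k < 2) stop("need at least 2 topics", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  s <- (k - 1) / (alpha * k)
  list(k = as.integer(k), alpha = alpha,
       mu0 = rep(0, k), sigma0sq = rep(s, k))
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Initialize encoder, decoder and survival-head parameters
#'
#' @param d vocabulary size; @param k number of topics;
#' @param d_hidden encoder embedding width (default 100);
#' @param decoder \code{"lda"} or \code{"sage"};
#' @param survival \code{"cox"}, \code{"aft"} or \code{"none"}.
#' @param init_scale standard deviation of decoder logit initialization.
#' @return named list of parameter arrays. Coefficient vectors store all k
#'   entries; the background (k-th) entry is pinned to 0 by the training
#'   code and its gradient is zeroed.
#' @keywords internal
init_params <- function(d, k, d_hidden = 100L, decoder = c("lda", "sage"),
                        survival = c("cox", "aft", "none"),
                        init_scale = 0.1) {
  decoder <- match.arg(decoder)
  survival <- match.arg(survival)
  glorot <- function(nin, nout)
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  p <- list(
    We = glorot(d, d_hidden), be = rep(0, d_hidden),
    Wmu = glorot(d_hidden, k), bmu = rep(0, k),
    Wsig = glorot(d_hidden, k), bsig = rep(0, k),
    H = matrix(stats::rnorm(k * d, sd = init_scale), k, d))
  if (decoder == "sage") p$gamma <- rep(0, d)
  if (survival == "cox") p$beta <- rep(0, k)
  if (survival == "aft") {
    p$theta <- rep(0, k)
    p$mu_aft <- 0
    p$log_sigma_aft <- stats::rnorm(1, sd = 1e-2)
  }
  p
}

#' Encode normalized counts into a Gaussian posterior over topic logits
#'
#' One softplus hidden layer maps the normalized count vector to an embedding
#' \eqn{\pi}; two affine heads map \eqn{\pi} to the posterior mean \eqn{\mu}
#' and log-variance \eqn{\log\sigma^2} of the unnormalized topic weights.
#' Deterministic given parameters (no dropout/batch statistics).
#'
#' @param xbar matrix (rows = subjects) or single vector of normalized counts.
#' @param params parameter list from \code{init_params} (fields \code{We},
#'   \code{be}, \code{Wmu}, \code{bmu}, \code{Wsig}, \code{bsig}).
#' @return list with matrices \code{mu} and \code{logsig2} (n x k).
#' @export
encode <- function(xbar, params) {
  if (is.null(dim(xbar))) xbar <- matrix(xbar, nrow = 1)
  if (ncol(xbar) != nrow(params$We))
    stop("input dimension does not match encoder", call. = FALSE)
  Z1 <- sweep(xbar %*% params$We, 2L, params$be, "+")
  Pi <- softplus(Z1)
  list(mu = sweep(Pi %*% params$Wmu, 2L, params$bmu, "+"),
       logsig2 = sweep(Pi %*% params$Wsig, 2L, params$bsig, "+"))
}

#' Reparameterized draw of topic weights
#'
#' Maps a posterior \eqn{(\mu, \log\sigma^2)} and externally supplied
#' standard-normal noise to the simplex:
#' \eqn{W = \mathrm{softmax}(\mu + \sigma \odot \epsilon)}.
#'
#' @param post list with \code{mu}, \code{logsig2} (vectors or n x k
#'   matrices).
#' @param noise standard-normal draws, same shape as \code{mu}.
#' @return simplex vector / matrix of topic weights.
#' @export
sample_topic_weights <- function(post, noise) {
  mu <- post$mu; ls <- post$logsig2
  vec <- is.null(dim(mu))
  if (vec) { mu <- matrix(mu, 1); ls <- matrix(ls, 1); noise <- matrix(noise, 1) }
  if (!all(dim(noise) == dim(mu)))
    stop("noise must match the posterior shape", call. = FALSE)
  W <- softmax_rows(mu + exp(0.5 * ls) * noise)
  if (vec) drop(W) else W
}

#' Posterior-mean estimate of topic weights
#'
#' Averages \code{n_samples} reparameterized softmax draws; this is the
#' evaluation-time topic-weight estimate fed to fitted survival heads.
#'
#' @param post list with \code{mu}, \code{logsig2} (vector or n x k matrix).
#' @param n_samples number of Monte-Carlo draws (>= 1; default 100).
#' @param seed integer seed for the draws (caller's RNG is untouched).
#' @return simplex vector / n x k matrix \eqn{\hat W}.
#' @export
estimate_topic_weights <- function(post, n_samples = 100L, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  mu <- post$mu; ls <- post$logsig2
  vec <- is.null(dim(mu))
  if (vec) { mu <- matrix(mu, 1); ls <- matrix(ls, 1) }
  n <- nrow(mu); k <- ncol(mu)
  S <- exp(0.5 * ls)
  acc <- matrix(0, n, k)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      E <- matrix(stats::rnorm(n * k), n, k)
      acc <- acc + softmax_rows(mu + S * E)
    }
  })
  W <- acc / n_samples
  if (vec) drop(W) else W
}

#' Per-subject word distribution under the decoder
#'
#' LDA decoder: \eqn{\zeta = W^\top A} with \eqn{A_g =
#' \mathrm{softmax}(H_g)} — a mixture of the per-topic word distributions.
#' SAGE decoder: \eqn{\zeta = \mathrm{softmax}(\gamma + W^\top H)} — topics
#' are log-deviations from a shared background log-frequency vector
#' \eqn{\gamma}.
#'
#' @param W topic-weight vector or n x k matrix (rows on the simplex).
#' @param decoder list with \code{kind} ("lda"/"sage"), \code{H} (k x d) and,
#'   for SAGE, \code{gamma} (length d).
#' @return word-distribution vector / n x d matrix, rows on the simplex.
#' @export
word_distribution <- function(W, decoder) {
  H <- decoder$H
  vec <- is.null(dim(W))
  if (vec) W <- matrix(W, 1)
  if (ncol(W) != nrow(H))
    stop("topic dimension does not match decoder", call. = FALSE)
  zeta <- if (identical(decoder$kind, "sage")) {
    softmax_rows(sweep(W %*% H, 2L, decoder$gamma, "+"))
  } else {
    W %*% softmax_rows(H)
  }
  if (vec) drop(zeta) else zeta
}

#' KL divergence from an encoded posterior to the topic prior
#'
#' Closed-form KL between the diagonal Gaussian \eqn{q = N(\mu,
#' \mathrm{diag}\,\sigma^2)} and the prior \eqn{N(0,\sigma_0^2 I)}:
#' \deqn{\tfrac12 \sum_g \left[ (\sigma_g^2 + \mu_g^2)/\sigma_0^2 - 1 +
#'   \log(\sigma_0^2/\sigma_g^2) \right].}
#' Zero exactly when \eqn{\mu = 0} and \eqn{\sigma^2 = \sigma_0^2}.
#'
#' @param post list with \code{mu}, \code{logsig2} (vector or matrix).
#' @param prior from \code{\link{prior_constants}}.
#' @return nonnegative scalar (vector input) or per-subject vector.
#' @export
kl_to_prior <- function(post, prior) {
  mu <- post$mu; ls <- post$logsig2
  vec <- is.null(dim(mu))
  if (vec) { mu <- matrix(mu, 1); ls <- matrix(ls, 1) }
  sig2 <- exp(ls)
  if (any(!is.finite(sig2)) || any(sig2 <= 0))
    stop("posterior variances must be positive and finite", call. = FALSE)
  s0 <- prior$sigma0sq[1]
  kl <- 0.5 * rowSums((sig2 + mu^2) / s0 - 1 + log(s0) - ls)
  if (vec) drop(kl) else kl
}

ZETA_FLOOR <- 1e-10

#' Topic-model loss (reconstruction + KL, batch mean)
#'
#' Per subject: the cross-entropy between normalized counts and the decoded
#' word distribution, \eqn{-\sum_v \bar X_{i,v}\log\zeta_{i,v}}, plus the KL
#' of the encoded posterior to the prior; averaged over the batch. For a SAGE
#' decoder an \eqn{\ell_2} penalty
#' \eqn{\lambda_{\mathrm{dev}}\sum_{g,v}H_{g,v}^2} on the log-deviations is
#' added. \eqn{\zeta} is floored at 1e-10 before the log.
#'
#' @param xbar_batch n x d matrix of normalized counts.
#' @param zeta_batch n x d matrix of decoded word distributions.
#' @param posts list with \code{mu}, \code{logsig2} n x k matrices.
#' @param prior from \code{\link{prior_constants}}.
#' @param decoder decoder list (used for the SAGE penalty); may be NULL.
#' @param lambda_small_deviation SAGE penalty weight (ignored for LDA).
#' @return scalar loss.
#' @export
topic_loss <- function(xbar_batch, zeta_batch, posts, prior,
                       decoder = NULL, lambda_small_deviation = 0) {
  if (lambda_small_deviation < 0)
    stop("lambda_small_deviation must be >= 0", call. = FALSE)
  recon <- -rowSums(xbar_batch * log(pmax(zeta_batch, ZETA_FLOOR)))
  kl <- kl_to_prior(posts, prior)
  loss <- mean(recon + kl)
  if (!is.null(decoder) && identical(decoder$kind, "sage") &&
      lambda_small_deviation > 0)
    loss <- loss + lambda_small_deviation * sum(decoder$H^2)
  loss
}

# --- train-time batch normalization (scale fixed at 1, shift = the head
# bias, which lets the normalization be absorbed into the affine head after
# training). Returns the standardized activations and the statistics needed
# for the backward pass.
BN_EPS <- 1e-5

bn_forward <- function(Xraw, shift) {
  m <- colMeans(Xraw)
  v <- colMeans(sweep(Xraw, 2L, m)^2)
  s <- sqrt(v + BN_EPS)
  Xhat <- sweep(sweep(Xraw, 2L, m), 2L, s, "/")
  list(Y = sweep(Xhat, 2L, shift, "+"), Xhat = Xhat, s = s, m = m, v = v)
}

bn_backward <- function(dY, Xhat, s) {
  # d/dXraw of y = (x - mean(x))/sqrt(var(x)+eps) + b, batch statistics
  dX <- sweep(dY, 2L, colMeans(dY)) - Xhat * rep(colMeans(dY * Xhat),
                                                 each = nrow(dY))
  sweep(dX, 2L, s, "/")
}

bn_state_init <- function(k, d, sage) {
  st <- list(mu_m = rep(0, k), mu_v = rep(1, k),
             lv_m = rep(0, k), lv_v = rep(1, k))
  if (sage) { st$eta_m <- rep(0, d); st$eta_v <- rep(1, d) }
  st
}

bn_update <- function(old, new, mom = 0.9) mom * old + (1 - mom) * new

# Fold the batch-normalization running statistics into the affine heads (and
# gamma/H for SAGE) so the returned parameters follow the plain architecture
# used by encode()/word_distribution().
absorb_bn <- function(params, bn, sage) {
  s_mu <- sqrt(bn$mu_v + BN_EPS); s_lv <- sqrt(bn$lv_v + BN_EPS)
  out <- params
  out$Wmu <- sweep(params$Wmu, 2L, s_mu, "/")
  out$bmu <- params$bmu - bn$mu_m / s_mu
  out$Wsig <- sweep(params$Wsig, 2L, s_lv, "/")
  out$bsig <- params$bsig - bn$lv_m / s_lv
  if (sage && !is.null(bn$eta_m)) {
    s_eta <- sqrt(bn$eta_v + BN_EPS)
    out$H <- sweep(params$H, 2L, s_eta, "/")
    out$gamma <- params$gamma - bn$eta_m / s_eta
  }
  out
}

# ---------------------------------------------------------------------------
# Full forward/backward pass for one minibatch. Deterministic given (params,
# batch, noise). Returns loss components and, if grad = TRUE, analytic
# gradients for every parameter (background survival coefficients get zero
# gradient). Used by the trainer and by the finite-difference checks.
# With bn_state non-NULL, posterior-head (and SAGE logit) activations are
# batch-normalized with scale 1 and the head bias as shift; updated running
# statistics are returned for later absorption into the affine heads.
# ---------------------------------------------------------------------------
scholar_batch <- function(params, xbar, y, delta, noise, prior, config,
                          grad = TRUE, kl_weight = 1, bn_state = NULL,
                          x_enc = NULL) {
  B <- nrow(xbar); k <- prior$k
  sage <- identical(config$decoder, "sage")
  use_bn <- !is.null(bn_state)
  if (is.null(x_enc)) x_enc <- xbar   # encoder input (raw counts optional)
  # encoder
  Z1 <- sweep(x_enc %*% params$We, 2L, params$be, "+")
  Pi <- softplus(Z1)
  if (use_bn) {
    bmu <- bn_forward(Pi %*% params$Wmu, params$bmu)
    blv <- bn_forward(Pi %*% params$Wsig, params$bsig)
    Mu <- bmu$Y; Lv <- blv$Y
  } else {
    Mu <- sweep(Pi %*% params$Wmu, 2L, params$bmu, "+")
    Lv <- sweep(Pi %*% params$Wsig, 2L, params$bsig, "+")
  }
  Sd <- exp(0.5 * Lv)
  Wt <- Mu + Sd * noise
  W <- softmax_rows(Wt)
  # decoder
  if (sage) {
    if (use_bn) {
      beta_bn <- bn_forward(W %*% params$H, params$gamma)
      Eta <- beta_bn$Y
    } else {
      Eta <- sweep(W %*% params$H, 2L, params$gamma, "+")
    }
    Zeta <- softmax_rows(Eta)
  } else {
    A <- softmax_rows(params$H)
    Zeta <- W %*% A
  }
  ZetaF <- pmax(Zeta, ZETA_FLOOR)
  recon <- -rowSums(xbar * log(ZetaF))
  s0 <- prior$sigma0sq[1]
  kl <- 0.5 * rowSums((exp(Lv) + Mu^2) / s0 - 1 + log(s0) - Lv)
  tl <- mean(recon + kl_weight * kl)
  lam_dev <- config$lambda_small_deviation %||% 0
  if (sage && lam_dev > 0) tl <- tl + lam_dev * sum(params$H^2)

  # survival term on the sampled topic weights
  surv <- 0; dscore <- NULL
  surv_kind <- config$survival %||% "none"
  if (surv_kind == "cox") {
    score <- drop(W %*% params$beta)
    cl <- cox_loss_with_grad(score, y, delta)
    surv <- cl$loss; dscore <- cl$grad
  } else if (surv_kind == "aft") {
    g <- drop(W %*% params$theta)            # linear part, theta_k = 0
    loc <- g + params$mu_aft
    sig <- exp(params$log_sigma_aft)
    al <- aft_nll_with_grad(loc, params$log_sigma_aft, y, delta)
    lam_rank <- config$lambda_ranking %||% 0
    surv <- al$loss
    dscore <- al$dloc
    dlogsig <- al$dlogsig
    if (lam_rank > 0) {
      rl <- ranking_loss_with_grad(g, y, delta)
      surv <- surv + lam_rank * rl$loss
      dscore <- dscore + lam_rank * rl$grad
    }
  }
  lam_surv <- config$lambda_survival %||% 0
  total <- tl + lam_surv * surv
  out <- list(loss = total, topic = tl, survival = surv,
              recon = mean(recon), kl = mean(kl), W = W)
  if (use_bn) {
    ns <- bn_state
    ns$mu_m <- bn_update(ns$mu_m, bmu$m); ns$mu_v <- bn_update(ns$mu_v, bmu$v)
    ns$lv_m <- bn_update(ns$lv_m, blv$m); ns$lv_v <- bn_update(ns$lv_v, blv$v)
    if (sage) {
      ns$eta_m <- bn_update(ns$eta_m, beta_bn$m)
      ns$eta_v <- bn_update(ns$eta_v, beta_bn$v)
    }
    out$bn_state <- ns
  }
  if (!grad) return(out)

  # ---- backward ----
  dZeta <- -(xbar / ZetaF) / B
  dZeta[Zeta < ZETA_FLOOR] <- 0
  if (sage) {
    dEta <- Zeta * (dZeta - rowSums(dZeta * Zeta))
    dgamma <- colSums(dEta)
    if (use_bn) dEta <- bn_backward(dEta, beta_bn$Xhat, beta_bn$s)
    dH <- crossprod(W, dEta)
    dW <- dEta %*% t(params$H)
    if (lam_dev > 0) dH <- dH + 2 * lam_dev * params$H
  } else {
    dA <- crossprod(W, dZeta)
    dW <- dZeta %*% t(A)
    dH <- A * (dA - rowSums(dA * A))   # row-wise softmax backward
  }
  # survival gradient into W and head parameters
  dbeta <- dtheta <- dmu_aft <- dlogsig_aft <- NULL
  if (surv_kind == "cox") {
    dbeta <- lam_surv * drop(crossprod(W, dscore))
    dbeta[k] <- 0
    dW <- dW + lam_surv * outer(dscore, params$beta)
  } else if (surv_kind == "aft") {
    dtheta <- lam_surv * drop(crossprod(W, dscore))
    dtheta[k] <- 0
    dmu_aft <- lam_surv * sum(al$dloc)
    dlogsig_aft <- lam_surv * dlogsig
    dW <- dW + lam_surv * outer(dscore, params$theta)
  }
  # softmax backward (per row)
  dWt <- W * (dW - rowSums(dW * W))
  dMu <- dWt + kl_weight * (Mu / s0) / B
  dLv <- dWt * noise * Sd * 0.5 + kl_weight * 0.5 * (exp(Lv) / s0 - 1) / B
  dbmu <- colSums(dMu); dbsig <- colSums(dLv)
  if (use_bn) {
    dMu <- bn_backward(dMu, bmu$Xhat, bmu$s)
    dLv <- bn_backward(dLv, blv$Xhat, blv$s)
  }
  dPi <- dMu %*% t(params$Wmu) + dLv %*% t(params$Wsig)
  dZ1 <- dPi * stats::plogis(Z1)           # softplus'
  grads <- list(
    We = crossprod(x_enc, dZ1), be = colSums(dZ1),
    Wmu = crossprod(Pi, dMu), bmu = dbmu,
    Wsig = crossprod(Pi, dLv), bsig = dbsig,
    H = dH)
  if (sage) grads$gamma <- dgamma
  if (surv_kind == "cox") grads$beta <- dbeta
  if (surv_kind == "aft") {
    grads$theta <- dtheta
    grads$mu_aft <- dmu_aft
    grads$log_sigma_aft <- dlogsig_aft
  }
  out$grads <- grads
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
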