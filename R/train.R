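#' Training configuration for a survival-supervised topic model
#'
#' Collects the model and optimizer hyperparameters for the four joint
#' models (lda-cox, lda-aft, sage-cox, sage-aft) and the unsupervised stage
#' of the naive baseline (\code{lambda_survival = 0}).
#'
#' @param k number of topics (the k-th is the zero-coefficient background
#'   topic); @param alpha Dirichlet concentration of the topic prior.
#' @param decoder \code{"lda"} or \code{"sage"}.
#' @param survival \code{"cox"}, \code{"aft"}, or \code{"none"}.
#' @param lambda_survival weight of the survival loss (> 0 for supervised
#'   models; 0 turns supervision off).
#' @param lambda_ranking weight of the ranking regularizer (AFT only).
#' @param lambda_small_deviation l2 penalty on SAGE log-deviations.
#' @param d_hidden encoder embedding width.
#' @param learning_rate,beta1,beta2 Adam settings; the high first-moment
#'   momentum default (0.99) follows standard practice for neural topic
#'   models, where low momentum invites topic mode collapse.
#' @param batch_size minibatch size; Cox risk sets and ranking pairs are
#'   formed within the minibatch.
#' @param epochs training epochs.
#' @param kl_warmup_epochs epochs over which the KL term's weight is
#'   annealed linearly from ~0 to 1. Warm-up lets the decoder differentiate
#'   its topics before the prior can pull every posterior to its mean — the
#'   posterior-collapse failure mode of amortized variational topic models.
#' @param batch_norm batch-normalize the posterior-head outputs (and SAGE
#'   decoder logits) during training, with scale fixed at 1 and the head
#'   bias as the shift. This keeps the across-batch spread of the posterior
#'   means away from zero, which is what prevents all topics from collapsing
#'   onto the corpus mean; the running statistics are folded back into the
#'   affine heads after training, so the fitted model is architecture-
#'   identical to one trained without it.
#' @param init_posterior_logvar initial value of the log-variance head bias;
#'   a low value starts training with near-deterministic topic-weight draws,
#'   which keeps the reconstruction signal clean while the decoder's topics
#'   differentiate (the KL pulls the variance up toward the prior later).
#' @param encoder_input feed the encoder the row-normalized counts
#'   (default) or the raw counts; the reconstruction target is always the
#'   normalized matrix.
#' @param eval_every epochs between
#'   validation-concordance evaluations (the best-validation checkpoint is
#'   retained).
#' @param checkpoint_tol validation-concordance band treated as a tie when
#'   retaining checkpoints; within the band the most-trained parameters win.
#' @param n_samples_eval Monte-Carlo draws for evaluation-time topic weights.
#' @param seed integer seed governing initialization, shuffling and sampling.
#' @return list of class \code{training_config}.
#' @export
training_config <- function(k = 5L, alpha = 1, decoder = "lda",
                            survival = "cox", lambda_survival = 10,
                            lambda_ranking = 1, lambda_small_deviation = 1e-4,
                            d_hidden = 100L, learning_rate = 2e-3,
                            beta1 = 0.99, beta2 = 0.999,
                            batch_size = 256L, epochs = 200L,
                            kl_warmup_epochs = 150L, batch_norm = TRUE,
                            init_posterior_logvar = -3,
                            encoder_input = c("normalized", "raw"),
                            eval_every = 5L, checkpoint_tol = 0.02,
                            n_samples_eval = 100L, seed = 1L) {
  if (lambda_survival < 0 || lambda_ranking < 0 || lambda_small_deviation < 0)
    stop("loss weights must be >= 0", call. = FALSE)
  if (!decoder %in% c("lda", "sage")) stop("unknown decoder", call. = FALSE)
  if (!survival %in% c("cox", "aft", "none"))
    stop("unknown survival kind", call. = FALSE)
  structure(list(k = as.integer(k), alpha = alpha, decoder = decoder,
                 survival = survival, lambda_survival = lambda_survival,
                 lambda_ranking = lambda_ranking,
                 lambda_small_deviation = lambda_small_deviation,
                 d_hidden = as.integer(d_hidden),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 kl_warmup_epochs = as.integer(kl_warmup_epochs),
                 batch_norm = isTRUE(batch_norm),
                 init_posterior_logvar = init_posterior_logvar,
                 encoder_input = match.arg(encoder_input),
                 eval_every = as.integer(eval_every),
                 checkpoint_tol = checkpoint_tol,
                 n_samples_eval = as.integer(n_samples_eval),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Joint loss: topic term plus weighted survival term
#'
#' @param topic_term scalar topic-model loss.
#' @param survival_term scalar survival loss (Cox partial likelihood, or AFT
#'   NLL plus weighted ranking loss).
#' @param lambda_survival survival weight (> 0 for supervised training).
#' @return \code{topic_term + lambda_survival * survival_term}.
#' @export
joint_loss <- function(topic_term, survival_term, lambda_survival) {
  topic_term + lambda_survival * survival_term
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1 ^ state$t
  bc2 <- 1 - beta2 ^ state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a survival-supervised neural topic model
#'
#' Minimizes the joint loss (topic reconstruction + KL, plus
#' \code{lambda_survival} times the survival loss computed on the
#' within-batch reparameterized topic weights) by minibatch Adam. When a
#' validation corpus is given, validation concordance is evaluated every
#' \code{eval_every} epochs and the best-scoring parameters are retained.
#' After training, evaluation-mode topic weights for the training set are
#' computed and — for a Cox head — the Breslow baseline is fitted on them.
#'
#' @param corpus_train training \code{counts_corpus}.
#' @param corpus_val optional validation \code{counts_corpus}.
#' @param config a \code{training_config}.
#' @param verbose print per-epoch progress.
#' @return object of class \code{scholar_model} with elements \code{params},
#'   \code{config}, \code{prior}, \code{vocab}, \code{baseline} (Cox),
#'   \code{log} (per-epoch data frame), \code{What_train}.
#' @export
train_scholar <- function(corpus_train, corpus_val = NULL, config,
                          verbose = FALSE) {
  stopifnot(inherits(corpus_train, "counts_corpus"))
  X <- corpus_train$X
  n <- nrow(X); d <- ncol(X)
  xbar <- normalize_rows(X)
  prior <- prior_constants(config$k, config$alpha)
  if (config$survival == "aft" && any(corpus_train$time <= 0))
    stop("AFT training requires strictly positive observed times",
         call. = FALSE)

  set.seed(config$seed)
  params <- init_params(d, config$k, config$d_hidden, config$decoder,
                        config$survival)
  params$bsig <- rep(config$init_posterior_logvar %||% -3, config$k)
  x_enc_full <- if (identical(config$encoder_input %||% "normalized", "raw"))
    X else xbar
  if (config$decoder == "sage")   # background starts at corpus log-frequency
    params$gamma <- log(colMeans(xbar) + 1e-8)
  opt <- adam_init(params)
  sage <- config$decoder == "sage"
  bn <- if (isTRUE(config$batch_norm))
    bn_state_init(config$k, d, sage) else NULL
  eval_params <- function()
    if (is.null(bn)) params else absorb_bn(params, bn, sage)
  log_rows <- vector("list", config$epochs)
  best <- list(ctd = -Inf, recon = Inf, params = NULL)
  track_val <- !is.null(corpus_val) && config$survival != "none"

  warmup <- max(config$kl_warmup_epochs %||% 0L, 0L)
  for (epoch in seq_len(config$epochs)) {
    kl_w <- if (warmup > 0) min(1, epoch / warmup) else 1
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      B <- length(idx)
      noise <- matrix(stats::rnorm(B * config$k), B, config$k)
      res <- scholar_batch(params, xbar[idx, , drop = FALSE],
                           corpus_train$time[idx], corpus_train$event[idx],
                           noise, prior, config, grad = TRUE,
                           kl_weight = kl_w, bn_state = bn,
                           x_enc = x_enc_full[idx, , drop = FALSE])
      if (!is.finite(res$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      if (!is.null(bn)) bn <- res$bn_state
      upd <- adam_step(params, res$grads, opt, config$learning_rate,
                       config$beta1, config$beta2)
      params <- upd$params; opt <- upd$state
      # keep the background survival coefficient pinned at zero
      if (!is.null(params$beta)) params$beta[config$k] <- 0
      if (!is.null(params$theta)) params$theta[config$k] <- 0
      ep_loss <- ep_loss + res$loss * B
    }
    ep_loss <- ep_loss / n
    val_ctd <- NA_real_
    if (track_val &&
        (epoch %% config$eval_every == 0L || epoch == config$epochs)) {
      ep_params <- eval_params()
      val_ctd <- tryCatch(
        validation_ctd(ep_params, corpus_val, prior, config),
        error = function(e) NA_real_)
      # checkpoint rule: validation concordance on a few hundred subjects
      # carries sampling noise of roughly +/- 0.02, so checkpoints within
      # that band of the running best are treated as ties and the
      # most-trained (latest) one is retained; a genuine drop in validation
      # concordance stops the tracking
      if (!is.na(val_ctd) && val_ctd > best$ctd - (config$checkpoint_tol %||% 0.02))
        best <- list(ctd = max(best$ctd, val_ctd), params = ep_params)
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                    val_ctd = val_ctd)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val ctd %s", epoch, ep_loss,
                      ifelse(is.na(val_ctd), "-", sprintf("%.4f", val_ctd))))
  }
  params <- if (track_val && is.finite(best$ctd) && !is.null(best$params))
    best$params else eval_params()

  model <- structure(
    list(params = params, config = config, prior = prior,
         vocab = corpus_train$vocab,
         log = do.call(rbind, log_rows),
         best_val_ctd = if (is.finite(best$ctd)) best$ctd else NA_real_),
    class = "scholar_model")
  model$What_train <- predict_topic_weights(model, corpus_train)
  if (config$survival == "cox") {
    sc <- drop(model$What_train %*% params$beta)
    model$baseline <- breslow_baseline(sc, corpus_train$time,
                                       corpus_train$event)
  }
  model
}

# Validation concordance under the current parameters (eval-mode weights; for
# Cox, any strictly decreasing baseline yields the same ordering, so a
# Breslow baseline from the validation scores themselves is used).
validation_ctd <- function(params, corpus_val, prior, config) {
  validation_metrics(params, corpus_val, prior, config)$ctd
}

# Concordance plus held-out reconstruction cross-entropy (eval-mode topic
# weights) on the validation corpus.
validation_metrics <- function(params, corpus_val, prior, config) {
  xb <- normalize_rows(corpus_val$X)
  xe <- if (identical(config$encoder_input %||% "normalized", "raw"))
    corpus_val$X else xb
  post <- encode(xe, params)
  W <- estimate_topic_weights(post, config$n_samples_eval,
                              seed = config$seed + 1L)
  decoder <- list(kind = config$decoder, H = params$H, gamma = params$gamma)
  zeta <- word_distribution(W, decoder)
  recon <- -mean(rowSums(xb * log(pmax(zeta, ZETA_FLOOR))))
  ps <- head_prediction_set(params, config, W, corpus_val$time,
                            corpus_val$event, corpus_val$subject_ids)
  list(ctd = ctd_index(ps), recon = recon)
}

head_prediction_set <- function(params, config, W, time, event,
                                subject_ids = NULL) {
  if (config$survival == "cox") {
    sc <- drop(W %*% params$beta)
    bl <- breslow_baseline(sc, time, event)
    curves <- lapply(sc, cox_survival_curve, baseline = bl)
  } else {
    loc <- drop(W %*% params$theta) + params$mu_aft
    sig <- exp(params$log_sigma_aft)
    curves <- lapply(loc, survival_curve_loglogistic, sigma = sig)
  }
  prediction_set(curves, time, event, subject_ids)
}

#' @export
print.scholar_model <- function(x, ...) {
  cat(sprintf("scholar %s-%s model: k = %d topics, d = %d events\n",
              x$config$decoder, x$config$survival, x$prior$k,
              ncol(x$params$H)))
  if (!is.na(x$best_val_ctd))
    cat(sprintf("best validation Ctd: %.4f\n", x$best_val_ctd))
  invisible(x)
}

#' Evaluation-mode topic weights for a corpus
#'
#' Encodes normalized counts and averages \code{n_samples_eval}
#' reparameterized draws per subject.
#'
#' @param model a fitted \code{scholar_model}; @param corpus a
#'   \code{counts_corpus}; @param seed RNG seed for the draws.
#' @return n x k matrix of topic weights (rows on the simplex).
#' @export
predict_topic_weights <- function(model, corpus, seed = NULL) {
  if (is.null(seed)) seed <- model$config$seed + 2L
  xe <- if (identical(model$config$encoder_input %||% "normalized", "raw"))
    corpus$X else normalize_rows(corpus$X)
  post <- encode(xe, model$params)
  estimate_topic_weights(post, model$config$n_samples_eval, seed = seed)
}

#' Predicted survival curves for a corpus
#'
#' Cox models use the Breslow baseline fitted on the training set raised to
#' \eqn{\exp(\beta^\top \hat W)}; AFT models return closed-form log-logistic
#' curves.
#'
#' @inheritParams predict_topic_weights
#' @return a \code{prediction_set} for the corpus subjects.
#' @export
predict_survival <- function(model, corpus, seed = NULL) {
  W <- predict_topic_weights(model, corpus, seed = seed)
  if (model$config$survival == "cox") {
    sc <- drop(W %*% model$params$beta)
    curves <- lapply(sc, cox_survival_curve, baseline = model$baseline)
    prediction_set(curves, corpus$time, corpus$event, corpus$subject_ids)
  } else if (model$config$survival == "aft") {
    loc <- drop(W %*% model$params$theta) + model$params$mu_aft
    curves <- lapply(loc, survival_curve_loglogistic,
                     sigma = exp(model$params$log_sigma_aft))
    prediction_set(curves, corpus$time, corpus$event, corpus$subject_ids)
  } else stop("model has no survival head", call. = FALSE)
}

#' Naive two-stage baseline: unsupervised topics, then Cox on fixed weights
#'
#' Stage 1 trains the topic model with the survival loss switched off
#' (\code{lambda_survival = 0}). Stage 2 freezes all topic parameters,
#' computes evaluation-mode topic weights for the training subjects, and fits
#' the Cox coefficients (background pinned at zero) by full-batch minimization
#' of the partial-likelihood loss on those fixed weights.
#'
#' @inheritParams train_scholar
#' @return a \code{scholar_model} whose \code{beta} comes from the decoupled
#'   stage-2 fit.
#' @export
fit_two_stage_naive <- function(corpus_train, corpus_val = NULL, config,
                                verbose = FALSE) {
  cfg1 <- config
  cfg1$survival <- "none"
  cfg1$lambda_survival <- 0
  model <- train_scholar(corpus_train, corpus_val = NULL, cfg1,
                         verbose = verbose)
  W <- model$What_train
  k <- config$k
  nll <- function(bfree) {
    cox_loss_with_grad(drop(W %*% c(bfree, 0)), corpus_train$time,
                       corpus_train$event, grad = FALSE)$loss
  }
  gr <- function(bfree) {
    g <- cox_loss_with_grad(drop(W %*% c(bfree, 0)), corpus_train$time,
                            corpus_train$event)$grad
    drop(crossprod(W, g))[-k]
  }
  fit <- stats::optim(rep(0, k - 1), nll, gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  model$params$beta <- c(fit$par, 0)
  model$config$survival <- "cox"
  sc <- drop(W %*% model$params$beta)
  model$baseline <- breslow_baseline(sc, corpus_train$time,
                                     corpus_train$event)
  if (!is.null(corpus_val)) {
    model$best_val_ctd <- tryCatch(
      validation_ctd(model$params, corpus_val, model$prior, model$config),
      error = function(e) NA_real_)
  }
  model
}

#' Select the best configuration by validation concordance
#'
#' Trains one model per configuration and returns the configuration whose
#' validation concordance is highest; exact ties go to the earlier entry.
#'
#' @param grid nonempty list of \code{training_config}s.
#' @param corpus_train,corpus_val training and validation corpora.
#' @param verbose print progress.
#' @return list with \code{best} (config), \code{best_index},
#'   \code{val_ctd} (per-config vector), \code{models}.
#' @export
select_hyperparameters <- function(grid, corpus_train, corpus_val,
                                   verbose = FALSE) {
  if (length(grid) == 0) stop("empty configuration grid", call. = FALSE)
  models <- lapply(grid, function(cfg)
    train_scholar(corpus_train, corpus_val, cfg, verbose = verbose))
  ctds <- vapply(models, function(m) m$best_val_ctd, numeric(1))
  best <- select_best_index(ctds)
  list(best = grid[[best]], best_index = best, val_ctd = ctds,
       models = models)
}

# First index attaining the maximum (grid-order tie-break).
select_best_index <- function(ctds) which.max(ctds)
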