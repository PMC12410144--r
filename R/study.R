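#' Reference synthetic recovery study
#'
#' Runs the package's end-to-end validation study for one seed: generate a
#' synthetic lda-cox corpus (n = 2000, d = 30, k = 3 planted near-disjoint
#' topics, 30\% censoring), split 80/20 with 20\% of training held out for
#' validation, train the supervised scholar lda-cox model and the naive
#' two-stage baseline under the study configuration, and score topic
#' recovery, coefficient order agreement, and validation/test concordance.
#'
#' @param seed integer seed for generation, splitting and training.
#' @param n,d,k study dimensions (defaults are the reference conditions).
#' @param censor_frac target censoring fraction.
#' @param fit_naive also fit the two-stage baseline (default TRUE).
#' @param test_metrics also compute test-set concordance with a bootstrap
#'   interval (default FALSE; used by the acceptance script).
#' @param boot_B bootstrap replicates when \code{test_metrics} is TRUE.
#' @return list with \code{recovery_tv}, \code{order_agreement},
#'   \code{supervised_val_ctd}, \code{naive_val_ctd}, and (when requested)
#'   \code{test_ctd}, \code{ci_lower}, \code{ci_upper},
#'   \code{censoring_fraction}, plus the fitted \code{model} and study
#'   objects.
#' @export
run_recovery_study <- function(seed, n = 2000L, d = 30L, k = 3L,
                               censor_frac = 0.3, fit_naive = TRUE,
                               test_metrics = FALSE, boot_B = 1000L) {
  spec <- synthetic_spec(n = n, d = d, k = k, alpha = 0.3,
                         censor_frac = censor_frac, seed = seed)
  gen <- generate_synthetic(spec)
  parts <- split_dataset(gen$corpus, test_frac = 0.2,
                         val_frac_of_train = 0.2, seed = seed)
  cfg <- study_config(k = k, seed = seed)
  model <- train_scholar(parts$train, parts$validation, cfg)
  topics <- extract_topics(model)
  rec <- topic_recovery_error(topics$display, spec$A_true)
  agr <- tryCatch(
    coefficient_order_agreement(topics$coef, spec$beta_true,
                                rec$permutation),
    error = function(e) NA_real_)
  out <- list(recovery_tv = rec$error, order_agreement = agr,
              supervised_val_ctd = model$best_val_ctd,
              model = model, spec = spec, parts = parts)
  if (fit_naive) {
    naive <- fit_two_stage_naive(parts$train, parts$validation, cfg)
    out$naive_val_ctd <- naive$best_val_ctd
    out$naive <- naive
  }
  if (test_metrics) {
    ps <- predict_survival(model, parts$test)
    ci <- bootstrap_ci(ps, B = boot_B, seed = seed + 1L)
    out$test_ctd <- ctd_index(ps)
    out$ci_lower <- ci$lower
    out$ci_upper <- ci$upper
    out$censoring_fraction <- mean(gen$corpus$event == 0)
  }
  out
}

#' Configuration used by the reference recovery study
#' @param k number of topics; @param seed training seed.
#' @return a \code{training_config}.
#' @export
study_config <- function(k = 3L, seed = 1L) {
  training_config(k = k, alpha = 5, decoder = "lda", survival = "cox",
                  lambda_survival = 10, epochs = 600L,
                  kl_warmup_epochs = 525L, seed = seed)
}
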