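# survtopic

Survival-supervised neural topic models for bags of clinical events.

## The problem

Electronic health records represent a patient as counts of discrete
historical events — "sodium in the bottom quintile", "ever diagnosed with
diabetes" — alongside a right-censored time-to-event label (time of death,
or a censoring time for patients still alive at data cutoff). Two analysis
goals usually conflict: *predicting* survival accurately, and
*understanding* how features group into clinically meaningful states. Topic
models learn structure over features but ignore outcomes; survival models
predict outcomes but treat features independently.

`survtopic` trains both jointly. Each patient's event counts are explained
by a mixture of k latent **topics** (distributions over events, like a
topic–word matrix A in text modeling), and the patient's topic weight
vector W is simultaneously the covariate vector of a survival model:

* topic model: amortized variational inference for an LDA-style decoder
  (ζ = Wᵀ·rowsoftmax(H)) or a SAGE-style decoder
  (ζ = softmax(γ + WᵀH), topics as log-deviations from a background),
  with a logistic-normal prior approximating a symmetric Dirichlet(α);
* survival head: Cox proportional hazards
  (loss −1/n Σ δᵢ[βᵀWᵢ − log Σ_{Yⱼ≥Yᵢ} exp(βᵀWⱼ)], Breslow baseline,
  curves Ŝ(t|w) = Ŝ₀(t)^exp(βᵀw)) or a log-logistic accelerated failure
  time model (log T = μ + θᵀW + σε, censored likelihood plus a pairwise
  ranking loss);
* joint objective: L_topic + λ_survival · L_survival, minimized by
  minibatch Adam, with the k-th topic's coefficient pinned to 0 as a
  *background topic*.

Evaluation uses the time-dependent concordance index (fraction of
comparable patient pairs whose predicted survival curves, read at the
earlier patient's event time, order the pair correctly) with percentile
bootstrap confidence intervals, and interpretation produces filtered,
ordered topic heatmaps (events in <2% or >50% of patients are hidden,
topics sorted so the leftmost column carries the shortest survival).

## Worked example

```r
library(survtopic)

# a synthetic cohort with planted structure: 3 topics over 30 events,
# Cox survival driven by the topic weights, 30% censoring
spec <- synthetic_spec(n = 2000, d = 30, k = 3, alpha = 0.3,
                       censor_frac = 0.3, seed = 1)
gen   <- generate_synthetic(spec)
parts <- split_dataset(gen$corpus, test_frac = 0.2,
                       val_frac_of_train = 0.2, seed = 1)

cfg <- study_config(k = 3, seed = 1)   # lda-cox reference configuration
model <- train_scholar(parts$train, parts$validation, cfg)
model
#> scholar lda-cox model: k = 3 topics, d = 30 events
#> best validation Ctd: 0.6656

# how well were the planted topics recovered?
topics <- extract_topics(model)
rec <- topic_recovery_error(topics$display, spec$A_true)
round(rec$error, 3)
#> [1] 0.016
coefficient_order_agreement(topics$coef, spec$beta_true, rec$permutation)
#> [1] 1

# held-out predictive accuracy with a bootstrap interval
ps <- predict_survival(model, parts$test)
ctd_index(ps)
#> [1] 0.6591874
ci <- bootstrap_ci(ps, B = 1000, seed = 2)
c(ci$lower, ci$upper)
#> [1] 0.6230566 0.6942234
```

A recovery error of 0.016 means the estimated topic–event distributions
sit within 1.6% total-variation distance of the planted ones after optimal
topic matching; order agreement 1 means the fitted Cox coefficients rank
the planted risk topics correctly. The jointly trained model's validation
concordance of 0.67 against the 0.59 reached by the decoupled two-stage
baseline (`fit_two_stage_naive()` on the same data and seed) is the
supervision benefit the joint model exists for.

Interpretation of a fitted model:

```r
lay <- build_heatmap(model, parts$train, min_frac = 0.02, max_frac = 0.50)
plot(lay)                      # pheatmap if installed
heatmap_table(lay, model)      # tidy (topic, coefficient, word, value) table
```

A command-line wrapper for the same pipeline lives at
`inst/cli/survtopic.R` (subcommands `simulate`, `prepare`, `train`,
`evaluate`, `interpret`).

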