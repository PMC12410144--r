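Package: survtopic
Title: Survival-Supervised Neural Topic Models for Clinical Event Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly trains neural topic models (LDA- and SAGE-style decoders
    under an amortized-variational encoder) with survival heads (Cox
    proportional hazards with Breslow baseline, log-logistic accelerated
    failure time), so that patient-level bags of clinical events are
    summarized as latent topics that predict time-to-event outcomes.
    Includes evaluation via the time-dependent concordance index with
    bootstrap confidence intervals, filtered topic heatmap summaries, a
    naive two-stage LDA-then-Cox baseline, and a synthetic-data generator
    with planted topic and survival structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    pheatmap,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
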