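#' Save a fitted model as a plain-text checkpoint
#'
#' Writes \code{manifest.json} (dimensions, decoder/survival kinds, prior
#' constants, seed) and \code{params.json} (all parameter arrays at full
#' double precision) into a directory; the Breslow baseline, training log
#' and vocabulary travel along.
#'
#' @param model a \code{scholar_model}; @param dir target directory.
#' @return \code{dir}, invisibly.
#' @export
write_scholar_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- model$config
  manifest <- list(k = cfg$k, alpha = cfg$alpha, decoder = cfg$decoder,
                   survival = cfg$survival, d = ncol(model$params$H),
                   d_hidden = cfg$d_hidden, seed = cfg$seed,
                   n_samples_eval = cfg$n_samples_eval,
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pack <- function(p) if (is.matrix(p))
    list(dim = dim(p), data = as.numeric(p)) else list(data = as.numeric(p))
  jsonlite::write_json(lapply(model$params, pack),
                       file.path(dir, "params.json"), digits = NA)
  if (!is.null(model$baseline))
    jsonlite::write_json(unclass(model$baseline),
                         file.path(dir, "baseline.json"), digits = NA)
  if (!is.null(model$vocab))
    utils::write.csv(model$vocab, file.path(dir, "vocab.csv"),
                     row.names = FALSE)
  if (!is.null(model$log))
    utils::write.csv(model$log, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint written by \code{write_scholar_model}
#'
#' @param dir checkpoint directory.
#' @return a \code{scholar_model} (without \code{What_train}).
#' @export
read_scholar_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  cfg <- do.call(training_config, cfg[names(cfg) %in%
                                        names(formals(training_config))])
  raw <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = TRUE)
  params <- lapply(raw, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  model <- structure(
    list(params = params, config = cfg,
         prior = prior_constants(cfg$k, cfg$alpha),
         best_val_ctd = NA_real_),
    class = "scholar_model")
  bl <- file.path(dir, "baseline.json")
  if (file.exists(bl)) {
    b <- jsonlite::read_json(bl, simplifyVector = TRUE)
    model$baseline <- structure(
      list(death_times = as.numeric(b$death_times),
           hazards = as.numeric(b$hazards), surv = as.numeric(b$surv)),
      class = "baseline_survival")
  }
  vc <- file.path(dir, "vocab.csv")
  if (file.exists(vc))
    model$vocab <- utils::read.csv(vc, stringsAsFactors = FALSE,
                                   colClasses = c(bin_label = "character"))
  lg <- file.path(dir, "training_log.csv")
  if (file.exists(lg)) model$log <- utils::read.csv(lg)
  model
}
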