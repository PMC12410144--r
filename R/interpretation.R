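#' Extract per-topic word scores and survival coefficients
#'
#' LDA decoder: returns the rows of \eqn{A = \mathrm{rowsoftmax}(H)} —
#' probabilities of each event conditioned on the topic. SAGE decoder:
#' returns the raw log-deviations \eqn{H} together with the induced
#' single-topic distributions \eqn{\mathrm{softmax}(\gamma + H_g)} for
#' display; a log-deviation of 3 means the event occurs \eqn{e^3} times its
#' background frequency. The background topic's coefficient is exactly 0.
#'
#' @param model a fitted \code{scholar_model}.
#' @return list with \code{display} (k x d, simplex rows), \code{raw}
#'   (k x d; equals \code{display} for LDA, log-deviations for SAGE),
#'   \code{coef} (length-k survival coefficients), \code{coef_kind}
#'   ("beta" for Cox, "theta" for AFT, "none"), \code{decoder}.
#' @export
extract_topics <- function(model) {
  p <- model$params
  if (identical(model$config$decoder, "sage")) {
    display <- softmax_rows(sweep(p$H, 2L, p$gamma, "+"))
    raw <- p$H
  } else {
    display <- softmax_rows(p$H)
    raw <- display
  }
  if (!is.null(p$beta)) {
    coef <- p$beta; kind <- "beta"
  } else if (!is.null(p$theta)) {
    coef <- p$theta; kind <- "theta"
  } else {
    coef <- rep(0, nrow(p$H)); kind <- "none"
  }
  coef[length(coef)] <- 0
  list(display = display, raw = raw, coef = coef, coef_kind = kind,
       decoder = model$config$decoder)
}

#' Order event columns for display
#'
#' Events are ranked by their maximum display score across topics
#' (descending; exact ties keep vocabulary order). After ranking, all kept
#' bins of a categorical variable are pulled adjacent to that variable's
#' best-ranked bin, in \code{bin_index} order, so a discretized variable
#' reads as one block.
#'
#' @param A k x d display matrix (nonnegative).
#' @param vocab vocabulary data frame (see \code{\link{counts_corpus}}).
#' @param kept integer indices of columns that passed the prevalence filter
#'   (default: all).
#' @return integer vector of column indices in display order.
#' @export
order_features <- function(A, vocab, kept = seq_len(ncol(A))) {
  score <- apply(A[, kept, drop = FALSE], 2L, max)
  ranked <- kept[order(-score, seq_along(kept))]
  out <- integer(0); done <- logical(ncol(A))
  for (v in ranked) {
    if (done[v]) next
    var <- vocab$variable_name[v]
    grp <- kept[vocab$variable_name[kept] == var]
    grp <- grp[order(vocab$bin_index[grp])]
    out <- c(out, grp)
    done[grp] <- TRUE
  }
  out
}

#' Build a filtered, ordered topic heatmap layout
#'
#' Applies the prevalence filter to the corpus, orders topics by their
#' survival coefficient so that the leftmost column is the topic associated
#' with the shortest survival (decreasing \eqn{\beta} for Cox; increasing
#' \eqn{\theta} for AFT, where larger \eqn{\theta} means longer survival),
#' orders and groups event rows via \code{\link{order_features}}, and
#' truncates to roughly \code{max_features} rows counted after categorical
#' grouping (whole variable blocks are kept, so the count can exceed
#' \code{max_features} slightly). Purely a read of the fitted model.
#'
#' @param model fitted \code{scholar_model}; @param corpus the corpus
#'   supplying prevalences (must share the model's vocabulary size).
#' @param min_frac,max_frac prevalence bounds (defaults 2\% / 50\%).
#' @param max_features optional cap on displayed rows (post-grouping).
#' @param reweight optional display reweighting: \code{"none"} (raw
#'   per-topic probabilities, the default), \code{"tfidf"} (each
#'   probability damped by its log-ratio to the geometric mean across
#'   topics, highlighting topic-specific events), or \code{"idf"} (each
#'   event damped by the log inverse of its document frequency in the
#'   corpus, drawing out rarer events). Feature ordering uses the
#'   reweighted values; neither scheme alters the fitted model.
#' @return object of class \code{heatmap_layout}: \code{values}
#'   (features x topics display matrix), \code{topic_order},
#'   \code{coefficients} (aligned with \code{topic_order}),
#'   \code{coef_kind}, \code{feature_order}, \code{feature_labels},
#'   \code{settings}.
#' @export
build_heatmap <- function(model, corpus, min_frac = 0.02, max_frac = 0.50,
                          max_features = NULL,
                          reweight = c("none", "tfidf", "idf")) {
  reweight <- match.arg(reweight)
  topics <- extract_topics(model)
  d <- ncol(topics$display)
  if (d != nrow(corpus$vocab))
    stop("model and corpus vocabularies differ", call. = FALSE)
  if (reweight == "tfidf") {
    A <- pmax(topics$display, ZETA_FLOOR)
    geo <- exp(colMeans(log(A)))
    topics$display <- A * log(sweep(A, 2L, geo, "/"))
    topics$display <- pmax(topics$display, 0)
  } else if (reweight == "idf") {
    df <- pmax(colMeans(as.matrix(corpus$X) > 0), 1 / nrow(corpus$X))
    topics$display <- sweep(topics$display, 2L, log(1 / df), "*")
  }
  kept <- prevalence_filter(corpus, min_frac, max_frac)
  if (length(kept) == 0)
    stop("no features survive the prevalence filter", call. = FALSE)
  topic_order <- if (identical(topics$coef_kind, "theta"))
    order(topics$coef) else order(-topics$coef)
  feats <- order_features(topics$display, corpus$vocab, kept)
  if (!is.null(max_features) && length(feats) > max_features) {
    # cut at the variable-block boundary that first reaches the cap
    vars <- corpus$vocab$variable_name[feats]
    block_end <- cumsum(rle(vars)$lengths)
    stop_at <- block_end[which(block_end >= max_features)[1]]
    feats <- feats[seq_len(stop_at)]
  }
  values <- t(topics$display[topic_order, feats, drop = FALSE])
  labels <- paste0(corpus$vocab$variable_name[feats], ":",
                   corpus$vocab$bin_label[feats])
  rownames(values) <- labels
  colnames(values) <- sprintf("topic %d (%s=%.2f)", topic_order,
                              topics$coef_kind, topics$coef[topic_order])
  structure(list(values = values, topic_order = topic_order,
                 coefficients = topics$coef[topic_order],
                 coef_kind = topics$coef_kind,
                 feature_order = feats, feature_labels = labels,
                 settings = list(min_frac = min_frac, max_frac = max_frac,
                                 max_features = max_features,
                                 reweight = reweight)),
            class = "heatmap_layout")
}

#' @export
print.heatmap_layout <- function(x, ...) {
  cat(sprintf("heatmap layout: %d features x %d topics (filter [%g, %g])\n",
              nrow(x$values), ncol(x$values), x$settings$min_frac,
              x$settings$max_frac))
  invisible(x)
}

#' @export
as.matrix.heatmap_layout <- function(x, ...) x$values

#' Plot a heatmap layout
#'
#' Uses \pkg{pheatmap} when installed, otherwise a base-graphics image.
#' Row/column order is fixed by the layout (no clustering).
#'
#' @param x a \code{heatmap_layout}; @param ... passed to the device plotter.
#' @export
plot.heatmap_layout <- function(x, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(x$values, cluster_rows = FALSE, cluster_cols = FALSE,
                       ...)
  } else {
    V <- x$values[rev(seq_len(nrow(x$values))), , drop = FALSE]
    graphics::image(t(V), axes = FALSE, ...)
  }
  invisible(x)
}

#' Export a heatmap layout as a tidy table
#'
#' One row per (topic, feature) with both the display value and the raw
#' decoder value (identical for LDA; log-deviations for SAGE).
#'
#' @param layout a \code{heatmap_layout}; @param model the fitted model it
#'   came from.
#' @return data frame with columns \code{topic}, \code{coefficient},
#'   \code{word}, \code{display_value}, \code{raw_value}.
#' @export
heatmap_table <- function(layout, model) {
  topics <- extract_topics(model)
  rows <- expand.grid(f = seq_along(layout$feature_order),
                      t = seq_along(layout$topic_order))
  data.frame(
    topic = layout$topic_order[rows$t],
    coefficient = layout$coefficients[rows$t],
    word = layout$feature_labels[rows$f],
    display_value = layout$values[cbind(rows$f, rows$t)],
    raw_value = topics$raw[cbind(layout$topic_order[rows$t],
                                 layout$feature_order[rows$f])])
}
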