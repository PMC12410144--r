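#' Construct a bag-of-events survival corpus
#'
#' Bundles a subjects-by-events count matrix with per-subject right-censored
#' survival labels and a vocabulary describing each event column. This is the
#' input container for every model in the package: each subject is a
#' "document" whose "words" are binary historical clinical events, counted as
#' many times as they occurred.
#'
#' @param X n x d matrix (base or \code{Matrix} sparse) of nonnegative
#'   integer counts; rows are subjects, columns are events.
#' @param vocab data frame with one row per event column and columns
#'   \code{word_id}, \code{variable_name}, \code{bin_label}, \code{bin_index}.
#' @param time numeric vector of observed times \eqn{Y_i \ge 0} (survival
#'   time if the event was observed, censoring time otherwise).
#' @param event integer/logical vector of event indicators
#'   \eqn{\delta_i \in \{0,1\}} (1 = event observed, 0 = censored).
#' @param subject_ids character or integer vector of unique subject
#'   identifiers; defaults to \code{1:n}.
#' @param allow_zero_rows if \code{FALSE} (default) a subject with zero total
#'   counts is rejected: the normalized reconstruction loss is undefined for
#'   an empty document.
#'
#' @return An object of class \code{counts_corpus} with elements \code{X},
#'   \code{vocab}, \code{time}, \code{event}, \code{subject_ids}.
#' @export
counts_corpus <- function(X, vocab, time, event, subject_ids = NULL,
                          allow_zero_rows = FALSE) {
  X <- as_count_matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (is.null(subject_ids)) subject_ids <- seq_len(n)
  vocab <- as_vocab(vocab, d)
  event <- as.integer(event)
  time <- as.numeric(time)
  if (length(time) != n || length(event) != n || length(subject_ids) != n)
    stop("labels/subject_ids must have one entry per row of X", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("subject_ids must be unique", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("observed times must be finite and >= 0", call. = FALSE)
  if (!all(event %in% c(0L, 1L)))
    stop("event indicators must be 0 or 1", call. = FALSE)
  rs <- Matrix::rowSums(X)
  if (!allow_zero_rows && any(rs == 0)) {
    bad <- subject_ids[which(rs == 0)[1]]
    stop(sprintf(
      "subject '%s' has zero total event counts; drop it or merge events (empty documents are not modelable)",
      bad), call. = FALSE)
  }
  structure(
    list(X = X, vocab = vocab, time = time, event = event,
         subject_ids = subject_ids),
    class = "counts_corpus")
}

as_count_matrix <- function(X) {
  if (inherits(X, "sparseMatrix")) X <- as.matrix(X)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X)) || any(X < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  if (any(abs(X - round(X)) > 1e-8))
    stop("counts must be integer-valued", call. = FALSE)
  round(X)
}

as_vocab <- function(vocab, d) {
  if (is.null(vocab)) {
    vocab <- data.frame(word_id = paste0("w", seq_len(d)),
                        variable_name = paste0("w", seq_len(d)),
                        bin_label = "1", bin_index = 1L,
                        stringsAsFactors = FALSE)
  }
  vocab <- as.data.frame(vocab, stringsAsFactors = FALSE)
  need <- c("word_id", "variable_name", "bin_label", "bin_index")
  if (!all(need %in% names(vocab)))
    stop("vocab needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(vocab) != d)
    stop("vocab must have one row per column of X", call. = FALSE)
  key <- paste(vocab$variable_name, vocab$bin_label, sep = "\r")
  if (anyDuplicated(key))
    stop("(variable_name, bin_label) pairs must be unique", call. = FALSE)
  vocab$bin_index <- as.integer(vocab$bin_index)
  vocab
}

#' @export
print.counts_corpus <- function(x, ...) {
  cat(sprintf("counts_corpus: %d subjects x %d events; %d events observed (%.1f%% censored)\n",
              nrow(x$X), ncol(x$X), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' @export
dim.counts_corpus <- function(x) dim(x$X)

#' Subset a corpus by subject index
#' @param corpus a \code{counts_corpus}.
#' @param idx integer vector of row indices.
#' @return a \code{counts_corpus} restricted to the selected subjects.
#' @export
corpus_subset <- function(corpus, idx) {
  counts_corpus(corpus$X[idx, , drop = FALSE], corpus$vocab,
                corpus$time[idx], corpus$event[idx],
                corpus$subject_ids[idx])
}

#' Row-normalize a count matrix
#'
#' Divides each row by its total, so the subjects-by-events matrix becomes a
#' matrix of within-subject event frequencies. Normalization weights every
#' subject equally in the topic reconstruction loss even when total
#' measurement counts differ by orders of magnitude across subjects.
#'
#' @param X count matrix (or a \code{counts_corpus}, whose \code{X} is used).
#' @return matrix of the same shape whose rows sum to 1.
#' @export
normalize_rows <- function(X) {
  if (inherits(X, "counts_corpus")) X <- X$X
  X <- as.matrix(X)
  if (any(X < 0)) stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(X)
  if (any(rs == 0)) {
    bad <- rownames(X)[which(rs == 0)[1]]
    if (is.null(bad)) bad <- as.character(which(rs == 0)[1])
    stop(sprintf("row '%s' sums to zero and cannot be normalized", bad),
         call. = FALSE)
  }
  X / rs
}

#' Discretize a continuous measurement into quantile bins
#'
#' Maps each non-missing value to one of \code{n_bins} bins delimited by
#' empirical quantiles of the non-missing values (e.g. quintiles for
#' \code{n_bins = 5}). Duplicate quantile edges caused by heavy ties are
#' collapsed, which can reduce the effective number of bins. Missing values
#' receive \code{NA} (they contribute zero counts downstream).
#'
#' @param values numeric vector, possibly with \code{NA}s.
#' @param n_bins number of quantile bins (>= 1).
#' @return list with \code{bin} (integer vector, \code{NA} for missing) and
#'   \code{edges} (the collapsed quantile edges).
#' @export
discretize_quantiles <- function(values, n_bins) {
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 1)
    stop("n_bins must be a positive integer", call. = FALSE)
  n_bins <- as.integer(n_bins)
  ok <- !is.na(values)
  if (!any(ok)) stop("all values are missing; nothing to discretize",
                     call. = FALSE)
  v <- values[ok]
  edges <- unique(as.numeric(
    stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                    type = 7, names = FALSE)))
  bin <- rep(NA_integer_, length(values))
  if (length(edges) < 2) {
    bin[ok] <- 1L  # constant input: single collapsed bin
  } else {
    bin[ok] <- as.integer(cut(v, breaks = edges, include.lowest = TRUE,
                              labels = FALSE))
  }
  list(bin = bin, edges = edges)
}

#' Expand one discretized variable into event-count columns
#'
#' Turns a vector of raw measurements into the per-variable block of the
#' bag-of-events matrix: one column per quantile bin, counting 1 for the bin
#' the value falls in. Missing values contribute zero counts by default; with
#' \code{missing_indicator = TRUE} an extra column counts them explicitly.
#'
#' @param values numeric vector (one entry per subject), \code{NA} allowed.
#' @param n_bins number of quantile bins.
#' @param variable_name name used to label the generated vocabulary rows.
#' @param missing_indicator add an explicit missing-value event column.
#' @return list with \code{counts} (subjects x bins matrix) and \code{vocab}
#'   (matching vocabulary rows).
#' @export
events_from_values <- function(values, n_bins, variable_name = "var",
                               missing_indicator = FALSE) {
  disc <- discretize_quantiles(values, n_bins)
  nb <- max(disc$bin, na.rm = TRUE)
  counts <- matrix(0, length(values), nb + missing_indicator)
  ok <- !is.na(disc$bin)
  counts[cbind(which(ok), disc$bin[ok])] <- 1
  labels <- paste0("q", seq_len(nb))
  if (missing_indicator) {
    counts[!ok, nb + 1] <- 1
    labels <- c(labels, "missing")
  }
  vocab <- data.frame(word_id = paste(variable_name, labels, sep = "_"),
                      variable_name = variable_name, bin_label = labels,
                      bin_index = seq_along(labels),
                      stringsAsFactors = FALSE)
  list(counts = counts, vocab = vocab)
}

#' Filter event columns by prevalence
#'
#' Returns the indices of columns whose prevalence (fraction of subjects with
#' a positive count) lies in \code{[min_frac, max_frac]}. Intended as a
#' post-training display filter: events that are too rare explain too little
#' of the cohort, events that are too common do not discriminate topics. It
#' never mutates model parameters.
#'
#' @param X count matrix or \code{counts_corpus}.
#' @param min_frac,max_frac prevalence bounds in \code{[0, 1]}.
#' @return integer vector of kept column indices.
#' @export
prevalence_filter <- function(X, min_frac = 0.02, max_frac = 0.50) {
  if (inherits(X, "counts_corpus")) X <- X$X
  if (!(min_frac >= 0 && max_frac <= 1 && min_frac <= max_frac))
    stop("need 0 <= min_frac <= max_frac <= 1", call. = FALSE)
  prev <- colMeans(as.matrix(X) > 0)
  which(prev >= min_frac & prev <= max_frac)
}

#' Split a corpus into train / validation / test parts
#'
#' Subject-level simple random split: first \code{test_frac} of subjects are
#' held out as the test set, then \code{val_frac_of_train} of the remaining
#' training subjects form the validation set. Sizes are rounded
#' deterministically and the same seed always yields the same partition.
#'
#' @param corpus a \code{counts_corpus}.
#' @param test_frac fraction of all subjects held out for testing.
#' @param val_frac_of_train fraction of the non-test subjects held out for
#'   validation.
#' @param seed integer seed controlling the permutation.
#' @param stratify_by_event if \code{TRUE}, the permutation is drawn within
#'   the censored and uncensored strata separately so all three parts keep
#'   approximately the overall event rate.
#' @return list with \code{train}, \code{validation}, \code{test} corpora.
#' @export
split_dataset <- function(corpus, test_frac = 0.2, val_frac_of_train = 0.2,
                          seed = 1L, stratify_by_event = FALSE) {
  if (!(test_frac > 0 && test_frac < 1) ||
      !(val_frac_of_train > 0 && val_frac_of_train < 1))
    stop("fractions must lie strictly in (0, 1)", call. = FALSE)
  n <- nrow(corpus$X)
  n_test <- round(n * test_frac)
  n_trainval <- n - n_test
  n_val <- round(n_trainval * val_frac_of_train)
  n_train <- n_trainval - n_val
  if (min(n_test, n_val, n_train) < 1)
    stop("split would produce an empty partition; need a larger corpus",
         call. = FALSE)
  perm <- with_seed(seed, {
    if (stratify_by_event) {
      # interleave permuted strata so each contiguous block of the
      # permutation keeps the overall event rate
      g1 <- sample(which(corpus$event == 1))
      g0 <- sample(which(corpus$event == 0))
      ord <- order(c(seq(0, 1, length.out = length(g1)),
                     seq(0, 1, length.out = length(g0))))
      c(g1, g0)[ord]
    } else sample.int(n)
  })
  idx_test <- sort(perm[seq_len(n_test)])
  idx_val <- sort(perm[n_test + seq_len(n_val)])
  idx_train <- sort(perm[n_test + n_val + seq_len(n_train)])
  list(train = corpus_subset(corpus, idx_train),
       validation = corpus_subset(corpus, idx_val),
       test = corpus_subset(corpus, idx_test))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a corpus to plain-text files
#'
#' Writes \code{counts.mtx} (MatrixMarket sparse), \code{vocab.csv} and
#' \code{labels.csv} (columns \code{subject_id, time, event}) into \code{dir}.
#'
#' @param corpus a \code{counts_corpus}.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(corpus$X, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  utils::write.csv(corpus$vocab, file.path(dir, "vocab.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(subject_id = corpus$subject_ids, time = corpus$time,
               event = corpus$event),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a corpus written by \code{write_corpus}
#'
#' Accepts \code{counts.mtx} (MatrixMarket) or \code{counts.csv} (dense,
#' no header) for the count matrix.
#'
#' @param dir directory containing the corpus files.
#' @param allow_zero_rows passed through to \code{\link{counts_corpus}}.
#' @return a \code{counts_corpus}.
#' @export
read_corpus <- function(dir, allow_zero_rows = FALSE) {
  mtx <- file.path(dir, "counts.mtx")
  csv <- file.path(dir, "counts.csv")
  if (file.exists(mtx)) {
    X <- as.matrix(Matrix::readMM(mtx))
  } else if (file.exists(csv)) {
    X <- as.matrix(utils::read.csv(csv, header = FALSE))
  } else stop("no counts.mtx or counts.csv in ", dir, call. = FALSE)
  vocab <- utils::read.csv(file.path(dir, "vocab.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(bin_label = "character"))
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  counts_corpus(X, vocab, labels$time, labels$event, labels$subject_id,
                allow_zero_rows = allow_zero_rows)
}
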