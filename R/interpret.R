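#' Class-conditional position frequency matrix
#'
#' Empirical per-position base frequencies over the (optionally
#' label-filtered) records — the matrix behind a sequence logo. Unknown
#' bases are excluded from the counts, so rows sum to 1 whenever every
#' record is over \{A,C,G,T\}.
#'
#' @param dataset a `splice_dataset`
#' @param label_filter `"all"`, `"positive"` or `"negative"`
#' @return a `position_frequency_matrix`: list with `frequencies` (L x 4,
#'   columns A,C,G,T), `counts` (L x 4 integer), `n_records`, `site_type`,
#'   `label_filter`
#' @export
position_frequencies <- function(dataset,
                                 label_filter = c("all", "positive", "negative")) {
  stopifnot(inherits(dataset, "splice_dataset"))
  label_filter <- match.arg(label_filter)
  keep <- switch(label_filter,
                 all = seq_along(dataset$labels),
                 positive = which(dataset$labels == 1L),
                 negative = which(dataset$labels == 0L))
  if (length(keep) == 0L) {
    stop(sprintf("input error: no records left after filter '%s'", label_filter),
         call. = FALSE)
  }
  counts <- apply(encode_one_hot(dataset[keep]), c(2L, 3L), sum)
  totals <- rowSums(counts)                       # < n if unknown bases present
  freq <- counts / ifelse(totals == 0, 1, totals)
  structure(list(frequencies = freq, counts = counts,
                 n_records = length(keep), site_type = dataset$site_type,
                 label_filter = label_filter),
            class = "position_frequency_matrix")
}

#' Write / read a position frequency matrix
#'
#' Tab-separated `position, A, C, G, T` layout consumable by standard logo
#' tools; `read_pfm()` round-trips `write_pfm()` output.
#'
#' @param pfm a [position_frequencies()] result
#' @param path output TSV path
#' @return `write_pfm`: invisibly, `path`; `read_pfm`: an L x 4 frequency
#'   matrix
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "position_frequency_matrix"))
  df <- data.frame(position = seq_len(nrow(pfm$frequencies)), pfm$frequencies)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pfm
#' @export
read_pfm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- as.matrix(df[, ONE_HOT_BASES, drop = FALSE])
  rownames(m) <- NULL
  m
}

## a callable returning P(true site) per record, for sub-models and ensembles
true_site_probability <- function(object, batch) {
  if (inherits(object, "splice_submodel")) {
    predict_proba(object, batch)[, 2L]
  } else if (is.list(object) && !is.null(object$meta) && !is.null(object$members)) {
    predict_ensemble(object$meta, object$members, batch)$probability
  } else {
    stop("object must be a splice_submodel or a list(meta=, members=)",
         call. = FALSE)
  }
}

#' Occlusion importance profile
#'
#' Importance of position p is the mean drop in predicted true-site
#' probability when a `window`-wide span centred at p is zeroed out (the
#' all-zero rows are the same code unknown bases get, so occlusion stays
#' in-distribution for the encoder). Spans are clipped at the window edges.
#'
#' @param object a trained `splice_submodel`, or `list(meta =, members =)`
#'   for an ensemble
#' @param batch N x L x 4 one-hot array of (typically positive) records
#' @param window occluded span width in nt (>= 1)
#' @return numeric vector of length L of mean probability drops
#' @export
occlusion_importance <- function(object, batch, window = 3L) {
  X <- batch_tensor(batch)
  L <- dim(X)[2L]
  window <- as.integer(window)
  if (window < 1L || window > L) {
    stop(sprintf("input error: window %d outside [1, %d]", window, L),
         call. = FALSE)
  }
  base <- true_site_probability(object, X)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(L), function(p) {
    span <- max(1L, p - half):min(L, p - half + window - 1L)
    Xo <- X
    Xo[, span, ] <- 0
    mean(base - true_site_probability(object, Xo))
  }, numeric(1))
}
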