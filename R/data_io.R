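#' Construct a labelled splice-window dataset
#'
#' A `splice_dataset` holds fixed-length genomic DNA windows with binary
#' labels (1 = true splice site, 0 = false/decoy site), handled separately
#' for acceptor sites (consensus AG) and donor sites (consensus GT).
#'
#' @param sequences character vector of DNA windows over \{A,C,G,T,N\};
#'   stored upper-case. All must share `window_length`.
#' @param labels integer/numeric vector of 0/1, same length as `sequences`.
#' @param site_type `"acceptor"` or `"donor"`.
#' @param window_length window length in nucleotides; defaults to the length
#'   of the first sequence.
#' @param consensus_positions integer pair of 1-based inclusive positions of
#'   the consensus dinucleotide (AG for acceptor, GT for donor).
#'
#' @return an object of class `splice_dataset` with fields `sequences`,
#'   `labels`, `window_length`, `consensus_positions`, `site_type`.
#' @export
splice_dataset <- function(sequences, labels, site_type,
                           window_length = NULL, consensus_positions) {
  site_type <- match.arg(site_type, c("acceptor", "donor"))
  sequences <- toupper(as.character(sequences))
  labels <- as.integer(labels)
  if (length(sequences) != length(labels)) {
    stop("`sequences` and `labels` must have the same length", call. = FALSE)
  }
  if (any(!labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  if (is.null(window_length)) {
    if (length(sequences) == 0L) stop("window_length required for an empty dataset",
                                      call. = FALSE)
    window_length <- nchar(sequences[[1L]])
  }
  window_length <- as.integer(window_length)
  bad <- which(nchar(sequences) != window_length)
  if (length(bad) > 0L) {
    stop(sprintf(
      "dataset integrity error: record(s) %s have length != declared window length %d",
      paste(utils::head(bad, 5L), collapse = ", "), window_length), call. = FALSE)
  }
  consensus_positions <- as.integer(consensus_positions)
  if (length(consensus_positions) != 2L ||
      consensus_positions[2L] != consensus_positions[1L] + 1L ||
      consensus_positions[1L] < 1L || consensus_positions[2L] > window_length) {
    stop("consensus_positions must be two adjacent 1-based positions inside the window",
         call. = FALSE)
  }
  structure(
    list(sequences = sequences, labels = labels,
         window_length = window_length,
         consensus_positions = consensus_positions,
         site_type = site_type),
    class = "splice_dataset")
}

#' @export
print.splice_dataset <- function(x, ...) {
  cat(sprintf("splice_dataset: %d records (%d positive / %d negative), %s sites\n",
              length(x$sequences), sum(x$labels == 1L), sum(x$labels == 0L),
              x$site_type))
  cat(sprintf("  window length %d nt; consensus %s at positions %d-%d\n",
              x$window_length, consensus_dinucleotide(x$site_type),
              x$consensus_positions[1L], x$consensus_positions[2L]))
  invisible(x)
}

#' @export
length.splice_dataset <- function(x) length(x$sequences)

#' Subset a splice dataset by record index
#' @param x a `splice_dataset`
#' @param i integer or logical index over records
#' @param ... unused
#' @export
`[.splice_dataset` <- function(x, i, ...) {
  splice_dataset(x$sequences[i], x$labels[i], x$site_type,
                 window_length = x$window_length,
                 consensus_positions = x$consensus_positions)
}

#' Consensus dinucleotide for a site type
#'
#' @param site_type `"acceptor"` (AG) or `"donor"` (GT)
#' @return `"AG"` or `"GT"`
#' @export
consensus_dinucleotide <- function(site_type) {
  switch(match.arg(site_type, c("acceptor", "donor")),
         acceptor = "AG", donor = "GT")
}

## column order of the one-hot code: fixed everywhere
ONE_HOT_BASES <- c("A", "C", "G", "T")

#' One-hot encode a splice dataset
#'
#' Each window of length L becomes an L x 4 binary matrix with column order
#' (A, C, G, T): A -> (1,0,0,0), C -> (0,1,0,0), G -> (0,0,1,0),
#' T -> (0,0,0,1). Any other symbol (N, IUPAC ambiguity codes) becomes an
#' all-zero row, so unknown bases contribute nothing downstream.
#'
#' @param dataset a `splice_dataset`
#' @return a `one_hot_batch`: an N x L x 4 binary array whose row order
#'   matches the dataset's record order, with the labels attached as the
#'   `"labels"` attribute.
#' @export
encode_one_hot <- function(dataset) {
  stopifnot(inherits(dataset, "splice_dataset"))
  n <- length(dataset$sequences)
  L <- dataset$window_length
  bad <- which(nchar(dataset$sequences) != L)
  if (length(bad) > 0L) {
    stop(sprintf("dataset integrity error: record %d has length %d, expected %d",
                 bad[1L], nchar(dataset$sequences[bad[1L]]), L), call. = FALSE)
  }
  tensor <- array(0, dim = c(n, L, 4L),
                  dimnames = list(NULL, NULL, ONE_HOT_BASES))
  if (n > 0L) {
    chars <- matrix(unlist(strsplit(dataset$sequences, "", fixed = TRUE),
                           use.names = FALSE), nrow = n, byrow = TRUE)
    for (b in 1:4) {
      hit <- which(chars == ONE_HOT_BASES[b])        # index into n x L matrix
      if (length(hit) > 0L) {
        rec <- (hit - 1L) %% n + 1L
        pos <- (hit - 1L) %/% n + 1L
        tensor[cbind(rec, pos, b)] <- 1
      }
    }
  }
  structure(tensor, labels = dataset$labels, class = c("one_hot_batch", "array"))
}

#' Decode a one-hot batch back to DNA strings
#'
#' Inverse of [encode_one_hot()]: a valid one-hot row maps back to its base,
#' an all-zero row decodes to `"N"`.
#'
#' @param batch a `one_hot_batch` (N x L x 4 array)
#' @return character vector of N DNA strings
#' @export
decode_one_hot <- function(batch) {
  stopifnot(length(dim(batch)) == 3L, dim(batch)[3L] == 4L)
  n <- dim(batch)[1L]; L <- dim(batch)[2L]
  if (n == 0L) return(character(0))
  flat <- matrix(batch, nrow = n * L, ncol = 4L)   # (record, position) pairs x base
  if (any(flat != 0 & flat != 1)) {
    stop("encoding corruption: non-binary entries in one-hot batch", call. = FALSE)
  }
  rs <- rowSums(flat)
  if (any(rs > 1)) {
    stop("encoding corruption: one-hot row with sum > 1", call. = FALSE)
  }
  base <- rep("N", n * L)
  hot <- rs == 1
  base[hot] <- ONE_HOT_BASES[max.col(flat[hot, , drop = FALSE])]
  chars <- matrix(base, nrow = n, ncol = L)        # column-major matches flat order
  apply(chars, 1L, paste0, collapse = "")
}

## dialect table: window length and 1-based consensus positions per site type
.dialects <- list(
  hs3d_140       = list(window_length = 140L,
                        consensus = list(acceptor = c(69L, 70L), donor = c(71L, 72L))),
  splicedeep_602 = list(window_length = 602L,
                        consensus = list(acceptor = c(301L, 302L), donor = c(301L, 302L)))
)

## Reads either FASTA (leading ">") or one-sequence-per-line text.
read_sequence_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop(sprintf("empty input: %s contains no sequences", path), call. = FALSE)
  }
  if (startsWith(lines[[1L]], ">")) {
    hdr <- grepl("^>", lines)
    if (!hdr[[1L]]) stop(sprintf("malformed FASTA: %s", path), call. = FALSE)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, character(1), collapse = "")
    as.character(seqs)
  } else {
    lines
  }
}

#' Read a labelled splice-window dataset
#'
#' Positives and negatives ship in separate files (the layout of the public
#' splice-window collections), each either FASTA or one-sequence-per-line
#' text, auto-detected by a leading `">"`. Alternatively a single CSV with
#' header `sequence,label` may be given as `pos_path` (with `neg_path =
#' NULL`). Sequences are upper-cased; positives get label 1.
#'
#' @param pos_path path to positive (true-site) sequences, or a combined CSV
#' @param neg_path path to negative sequences, or `NULL` when `pos_path` is
#'   a combined CSV
#' @param dialect `"hs3d_140"` (140-nt windows, acceptor AG at 69-70, donor
#'   GT at 71-72), `"splicedeep_602"` (602-nt windows, consensus at 301-302),
#'   or `"generic"` (take geometry from `window_length`/`consensus_positions`)
#' @param site_type `"acceptor"` or `"donor"`
#' @param window_length,consensus_positions required for `dialect = "generic"`
#' @return a [splice_dataset()]
#' @export
read_dataset <- function(pos_path, neg_path = NULL,
                         dialect = c("hs3d_140", "splicedeep_602", "generic"),
                         site_type = c("acceptor", "donor"),
                         window_length = NULL, consensus_positions = NULL) {
  dialect <- match.arg(dialect)
  site_type <- match.arg(site_type)
  if (dialect != "generic") {
    d <- .dialects[[dialect]]
    window_length <- d$window_length
    consensus_positions <- d$consensus[[site_type]]
  } else if (is.null(window_length) || is.null(consensus_positions)) {
    stop("generic dialect requires window_length and consensus_positions",
         call. = FALSE)
  }
  if (is.null(neg_path)) {
    df <- utils::read.csv(pos_path, stringsAsFactors = FALSE)
    if (!all(c("sequence", "label") %in% names(df))) {
      stop("combined CSV must have columns `sequence` and `label`", call. = FALSE)
    }
    if (nrow(df) == 0L) stop(sprintf("empty input: %s", pos_path), call. = FALSE)
    seqs <- df$sequence; labels <- as.integer(df$label)
  } else {
    pos <- read_sequence_file(pos_path)
    neg <- read_sequence_file(neg_path)
    seqs <- c(pos, neg)
    labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  }
  splice_dataset(seqs, labels, site_type,
                 window_length = window_length,
                 consensus_positions = consensus_positions)
}

#' Write a splice dataset as a FASTA pair
#'
#' Fixture/export writer: positives and negatives go to two FASTA files with
#' headers carrying record index, site type, and label.
#'
#' @param dataset a `splice_dataset`
#' @param pos_path,neg_path output FASTA paths
#' @return invisibly, `c(pos_path, neg_path)`
#' @export
write_dataset_fasta <- function(dataset, pos_path, neg_path) {
  stopifnot(inherits(dataset, "splice_dataset"))
  write_one <- function(idx, path) {
    con <- file(path, "w"); on.exit(close(con))
    for (i in idx) {
      writeLines(c(sprintf(">record_%d %s label=%d", i, dataset$site_type,
                           dataset$labels[i]),
                   dataset$sequences[i]), con)
    }
  }
  write_one(which(dataset$labels == 1L), pos_path)
  write_one(which(dataset$labels == 0L), neg_path)
  invisible(c(pos_path, neg_path))
}

#' Report records whose consensus dinucleotide is violated
#'
#' Both true and decoy windows are expected to carry the consensus (AG for
#' acceptor, GT for donor) at the dataset's declared positions; a record
#' violates if and only if the dinucleotide there differs.
#'
#' @param dataset a non-empty `splice_dataset`
#' @return a list with `violations` (integer record indices),
#'   `positive_violations`, `negative_violations`, and `n_checked`
#' @export
validate_consensus <- function(dataset) {
  stopifnot(inherits(dataset, "splice_dataset"))
  if (length(dataset$sequences) == 0L) stop("empty dataset", call. = FALSE)
  cp <- dataset$consensus_positions
  din <- substr(dataset$sequences, cp[1L], cp[2L])
  bad <- which(din != consensus_dinucleotide(dataset$site_type))
  list(violations = bad,
       positive_violations = bad[dataset$labels[bad] == 1L],
       negative_violations = bad[dataset$labels[bad] == 0L],
       n_checked = length(dataset$sequences))
}

#' Deterministically subsample a class-balanced dataset
#'
#' Shuffles each class with a dedicated RNG seeded by `seed` and keeps the
#' first `n_per_class` records of each, mirroring the seeded-shuffle-then-
#' take-prefix subsampling convention of the public splice-window datasets
#' (default seed 123454).
#'
#' @param dataset a `splice_dataset`
#' @param n_per_class records to keep per class
#' @param seed RNG seed (default 123454)
#' @return a balanced `splice_dataset` with `2 * n_per_class` records
#'   (positives first)
#' @export
subsample_balance <- function(dataset, n_per_class, seed = 123454L) {
  stopifnot(inherits(dataset, "splice_dataset"))
  n_per_class <- as.integer(n_per_class)
  pos <- which(dataset$labels == 1L)
  neg <- which(dataset$labels == 0L)
  for (cls in list(c("positive", length(pos)), c("negative", length(neg)))) {
    have <- as.integer(cls[2L])
    if (have < n_per_class) {
      stop(sprintf(
        "insufficient data: %s class has %d records, need %d (deficit %d)",
        cls[1L], have, n_per_class, n_per_class - have), call. = FALSE)
    }
  }
  idx <- with_seed(seed, {
    c(sample(pos)[seq_len(n_per_class)], sample(neg)[seq_len(n_per_class)])
  })
  dataset[idx]
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`;
## the caller's RNG state is untouched.
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
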