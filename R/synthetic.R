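#' Build a default position-weight-matrix motif for a splice window
#'
#' Background positions get uniform base probabilities (0.25 each); within a
#' +/- 6 nt neighbourhood of the consensus dinucleotide one base per position
#' is enriched to `0.25 + 0.75 * sharpness` (the others renormalised), which
#' mimics the extended donor/acceptor signal seen around real splice sites.
#' Rows at the consensus positions are deterministic (probability 1 on A,G or
#' G,T).
#'
#' @param site_type `"acceptor"` or `"donor"`
#' @param window_length window length in nucleotides
#' @param consensus_positions 1-based pair of adjacent consensus positions
#' @param sharpness in `[0,1]`; 0 gives a uniform PWM away from the
#'   consensus, 1 makes the enriched neighbourhood deterministic
#' @return a `motif_model`: list with `pwm` (L x 4, rows sum to 1, columns
#'   A,C,G,T), `consensus_positions`, `consensus_dinucleotide`
#' @export
default_motif <- function(site_type, window_length, consensus_positions,
                          sharpness = 0.8) {
  site_type <- match.arg(site_type, c("acceptor", "donor"))
  window_length <- as.integer(window_length)
  cp <- as.integer(consensus_positions)
  if (length(cp) != 2L || cp[1L] < 1L || cp[2L] > window_length ||
      cp[2L] != cp[1L] + 1L) {
    stop("config error: consensus positions outside window or not adjacent",
         call. = FALSE)
  }
  stopifnot(sharpness >= 0, sharpness <= 1)
  pwm <- matrix(0.25, nrow = window_length, ncol = 4L,
                dimnames = list(NULL, ONE_HOT_BASES))
  nb <- setdiff(intersect(seq.int(cp[1L] - 6L, cp[2L] + 6L),
                          seq_len(window_length)), cp)
  for (p in nb) {
    fav <- (p %% 4L) + 1L      # deterministic, position-dependent enriched base
    q <- 0.25 + 0.75 * sharpness
    pwm[p, ] <- (1 - q) / 3
    pwm[p, fav] <- q
  }
  din <- strsplit(consensus_dinucleotide(site_type), "")[[1L]]
  for (j in 1:2) {
    pwm[cp[j], ] <- 0
    pwm[cp[j], din[j]] <- 1
  }
  structure(list(pwm = pwm, consensus_positions = cp,
                 consensus_dinucleotide = paste0(din, collapse = "")),
            class = "motif_model")
}

#' Synthetic splice-window generation settings
#'
#' @param n_per_class records per class (>= 1)
#' @param window_length window length in nucleotides
#' @param site_type `"acceptor"` or `"donor"`
#' @param signal_strength in `[0,1]`: positives sample their flanks from the
#'   mixture `signal_strength * pwm + (1 - signal_strength) * background`;
#'   0 makes positives indistinguishable from negatives away from the
#'   consensus, 1 draws them exactly from the PWM
#' @param background length-4 base probability vector (A,C,G,T), normalised
#' @param seed master RNG seed; per-class streams are derived from it
#' @param decoy_consensus if `TRUE` (default) negatives also carry the
#'   consensus dinucleotide, matching how decoy false sites are defined
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_per_class, window_length,
                             site_type = c("donor", "acceptor"),
                             signal_strength = 1.0,
                             background = rep(0.25, 4),
                             seed = 1L,
                             decoy_consensus = TRUE) {
  site_type <- match.arg(site_type)
  stopifnot(n_per_class >= 1, signal_strength >= 0, signal_strength <= 1,
            length(background) == 4L, all(background >= 0), sum(background) > 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 window_length = as.integer(window_length),
                 site_type = site_type,
                 signal_strength = signal_strength,
                 background = background / sum(background),
                 seed = as.integer(seed),
                 decoy_consensus = isTRUE(decoy_consensus)),
            class = "synthetic_config")
}

## Sample n sequences of length L, position p drawn from prob[p, ] (L x 4).
sample_from_pwm <- function(n, prob) {
  L <- nrow(prob)
  chars <- matrix("", nrow = n, ncol = L)
  for (p in seq_len(L)) {
    chars[, p] <- sample(ONE_HOT_BASES, n, replace = TRUE, prob = prob[p, ])
  }
  apply(chars, 1L, paste0, collapse = "")
}

#' Generate a labelled synthetic splice-window dataset
#'
#' Positives draw each flank position from the mixture
#' `signal_strength * pwm + (1 - signal_strength) * background`; negatives
#' draw flanks from the background alone. Both classes carry the consensus
#' dinucleotide at the declared positions (negatives are decoys) unless
#' `decoy_consensus` is disabled in the config. Classes are exactly
#' balanced, positives first, and the output is bit-identical for a fixed
#' `(config, motif)` pair: the positive and negative classes use separate
#' RNG streams derived from the master seed.
#'
#' @param config a [synthetic_config()]
#' @param motif a [default_motif()] result (PWM length must equal the
#'   config's window length)
#' @return a [splice_dataset()] of `2 * n_per_class` records
#' @export
generate_dataset <- function(config, motif) {
  stopifnot(inherits(config, "synthetic_config"), inherits(motif, "motif_model"))
  L <- config$window_length
  if (nrow(motif$pwm) != L) {
    stop(sprintf("config error: motif length %d != window length %d",
                 nrow(motif$pwm), L), call. = FALSE)
  }
  n <- config$n_per_class
  s <- config$signal_strength
  bg <- matrix(config$background, nrow = L, ncol = 4L, byrow = TRUE,
               dimnames = list(NULL, ONE_HOT_BASES))
  pos_prob <- s * motif$pwm + (1 - s) * bg
  neg_prob <- bg
  cp <- motif$consensus_positions
  din <- strsplit(motif$consensus_dinucleotide, "")[[1L]]
  force_consensus <- function(prob) {
    for (j in 1:2) { prob[cp[j], ] <- 0; prob[cp[j], din[j]] <- 1 }
    prob
  }
  pos_prob <- force_consensus(pos_prob)   # consensus always present in positives
  if (config$decoy_consensus) neg_prob <- force_consensus(neg_prob)
  ## separate derived streams so one class's draw count cannot perturb the other
  pos_seqs <- with_seed(config$seed * 2L + 1L, sample_from_pwm(n, pos_prob))
  neg_seqs <- with_seed(config$seed * 2L + 2L, sample_from_pwm(n, neg_prob))
  splice_dataset(c(pos_seqs, neg_seqs), c(rep(1L, n), rep(0L, n)),
                 config$site_type, window_length = L,
                 consensus_positions = cp)
}

#' Write a synthetic dataset to disk
#'
#' Writes the FASTA pair via [write_dataset_fasta()] plus a CSV manifest
#' recording the generation settings.
#'
#' @param dataset a `splice_dataset`
#' @param config the `synthetic_config` that produced it
#' @param dir output directory (created if needed)
#' @return invisibly, named vector of written paths
#' @export
write_synthetic <- function(dataset, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- file.path(dir, sprintf("%s_positive.fa", config$site_type))
  neg <- file.path(dir, sprintf("%s_negative.fa", config$site_type))
  write_dataset_fasta(dataset, pos, neg)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(
    site_type = config$site_type, n_per_class = config$n_per_class,
    window_length = config$window_length,
    signal_strength = config$signal_strength, seed = config$seed,
    decoy_consensus = config$decoy_consensus,
    consensus_start = dataset$consensus_positions[1L],
    positive_fasta = basename(pos), negative_fasta = basename(neg)),
    manifest, row.names = FALSE)
  invisible(c(positive = pos, negative = neg, manifest = manifest))
}
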