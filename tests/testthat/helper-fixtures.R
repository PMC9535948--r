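## Shared fixtures and independent oracles for the test suite.

random_sequences <- function(n, L, alphabet = c("A", "C", "G", "T"), seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste0(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

## small labelled dataset with the consensus planted in every record
tiny_dataset <- function(n_per_class = 10, L = 12, site_type = "donor",
                         cp = c(5L, 6L), seed = 1) {
  seqs <- random_sequences(2 * n_per_class, L, seed = seed)
  din <- strsplit(spliceStack::consensus_dinucleotide(site_type), "")[[1]]
  substr(seqs, cp[1], cp[1]) <- din[1]
  substr(seqs, cp[2], cp[2]) <- din[2]
  spliceStack::splice_dataset(seqs, rep(c(1L, 0L), each = n_per_class),
                              site_type, window_length = L,
                              consensus_positions = cp)
}

## a degenerate sub-model emitting a constant prediction: zero weights,
## bias picked so the argmax is forced
constant_model <- function(label, L, name = sprintf("const%d", label)) {
  spec <- spliceStack::submodel_spec(name, list(spliceStack::flatten(),
                                                spliceStack::dense(2, "sigmoid")))
  m <- spliceStack::build_submodel(spec, L, seed = 1)
  i <- length(m$layers)
  m$layers[[i]]$W[] <- 0
  m$layers[[i]]$b <- if (label == 1L) c(-5, 5) else c(5, -5)
  m$trained <- TRUE
  m
}

quick_config <- function(max_epochs = 2, seed = 1, ...) {
  spliceStack::train_config(max_epochs = max_epochs, seed = seed, ...)
}

## ---- independent oracles ---------------------------------------------------

## direct evaluation of the seven evaluation-metric formulas, written
## independently of metric_report (integer products stay exact in doubles
## for the count ranges used in tests)
oracle_metrics <- function(TP, TN, FP, FN) {
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  n <- TP + TN + FP + FN
  div <- function(a, b) if (b == 0) 0 else a / b
  mcc_d <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(accuracy = (TP + TN) / n,
       precision = div(TP, TP + FP),
       sensitivity = div(TP, TP + FN),
       specificity = div(TN, TN + FP),
       mcc = if (mcc_d == 0) 0 else (TP * TN - FP * FN) / sqrt(mcc_d),
       f1 = div(2 * TP, 2 * TP + FP + FN),
       error_rate = 1 - (TP + TN) / n)
}

## brute-force K^ij enumeration (explicit record loop) + direct formulas
oracle_diversity <- function(a, b) {
  K11 <- 0L; K10 <- 0L; K01 <- 0L; K00 <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) K11 <- K11 + 1L
    else if (a[i] == 1 && b[i] == 0) K10 <- K10 + 1L
    else if (a[i] == 0 && b[i] == 1) K01 <- K01 + 1L
    else K00 <- K00 + 1L
  }
  n <- K11 + K10 + K01 + K00
  num <- as.numeric(K11) * K00 - as.numeric(K01) * K10
  cd <- as.numeric(K11 + K10) * (K01 + K00) * (K11 + K01) * (K10 + K00)
  qd <- as.numeric(K11) * K00 + as.numeric(K01) * K10
  list(K = c(K11 = K11, K10 = K10, K01 = K01, K00 = K00),
       correlation = if (cd == 0) 0 else num / sqrt(cd),
       double_fault = K00 / n,
       disagreement = (K01 + K10) / n,
       q_statistic = if (qd == 0) 0 else num / qd)
}
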