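#' Confusion counts
#'
#' Standard 2x2 tabulation of binary predictions against truth with label 1
#' (true splice site) as the positive class.
#'
#' @param pred,truth equal-length binary vectors
#' @return a `confusion_counts` list with TP, TN, FP, FN
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth) || length(pred) < 1L) {
    stop("input error: pred and truth must be equal-length, non-empty",
         call. = FALSE)
  }
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 TN = sum(pred == 0L & truth == 0L),
                 FP = sum(pred == 1L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L)),
            class = "confusion_counts")
}

## ratio with the zero-denominator policy: 0 plus a degeneracy flag
safe_ratio <- function(num, den, flags, name) {
  if (den == 0) {
    flags[[name]] <- TRUE
    list(value = 0, flags = flags)
  } else {
    list(value = num / den, flags = flags)
  }
}

#' Evaluation-metric report from confusion counts
#'
#' Computes accuracy, precision, sensitivity, specificity, Matthews
#' correlation coefficient, F1 and error rate:
#' \deqn{Acc = (TP+TN)/n,\; Pre = TP/(TP+FP),\; Sn = TP/(TP+FN),}
#' \deqn{Sp = TN/(TN+FP),\; F1 = 2TP/(2TP+FP+FN),\; Err = 1 - Acc,}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' A ratio with zero denominator is reported as 0 and the metric name added
#' to the `degenerate` attribute, so cross-validation aggregation never
#' aborts on a pathological fold.
#'
#' @param counts a [confusion_counts()]
#' @return a `metric_report` list: accuracy, precision, sensitivity,
#'   specificity, mcc, f1, error_rate; attribute `degenerate` lists metrics
#'   whose denominator was zero
#' @export
metric_report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ## doubles: count products overflow 32-bit integers
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  n <- TP + TN + FP + FN
  if (n == 0) stop("input error: all confusion counts are zero", call. = FALSE)
  flags <- list()
  acc <- (TP + TN) / n
  r <- safe_ratio(TP, TP + FP, flags, "precision"); pre <- r$value; flags <- r$flags
  r <- safe_ratio(TP, TP + FN, flags, "sensitivity"); sn <- r$value; flags <- r$flags
  r <- safe_ratio(TN, TN + FP, flags, "specificity"); sp <- r$value; flags <- r$flags
  r <- safe_ratio(2 * TP, 2 * TP + FP + FN, flags, "f1"); f1 <- r$value; flags <- r$flags
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  if (mcc_den == 0) {
    flags$mcc <- TRUE; mcc <- 0
  } else {
    mcc <- (TP * TN - FP * FN) / mcc_den
  }
  structure(list(accuracy = acc, precision = pre, sensitivity = sn,
                 specificity = sp, mcc = mcc, f1 = f1, error_rate = 1 - acc),
            degenerate = names(flags), class = "metric_report")
}

#' Pairwise correctness contingency
#'
#' Tabulates two classifiers' correctness indicators (1 = classifier right on
#' that record): `K11` both right, `K10` only the first right, `K01` only the
#' second, `K00` both wrong.
#'
#' @param correct_a,correct_b equal-length binary correctness vectors
#' @return a `pair_contingency` list with K11, K10, K01, K00
#' @export
pair_contingency <- function(correct_a, correct_b) {
  a <- as.integer(correct_a); b <- as.integer(correct_b)
  if (length(a) != length(b) || length(a) < 1L) {
    stop("input error: correctness vectors must be equal-length, non-empty",
         call. = FALSE)
  }
  stopifnot(all(a %in% 0:1), all(b %in% 0:1))
  structure(list(K11 = sum(a == 1L & b == 1L),
                 K10 = sum(a == 1L & b == 0L),
                 K01 = sum(a == 0L & b == 1L),
                 K00 = sum(a == 0L & b == 0L)),
            class = "pair_contingency")
}

#' Pairwise diversity metrics
#'
#' From a correctness contingency computes:
#' correlation \eqn{(K^{11}K^{00}-K^{01}K^{10})/\sqrt{(K^{11}+K^{10})(K^{01}+K^{00})(K^{11}+K^{01})(K^{10}+K^{00})}},
#' double fault \eqn{K^{00}/n}, disagreement \eqn{(K^{01}+K^{10})/n} and
#' Yule's Q-statistic
#' \eqn{(K^{11}K^{00}-K^{01}K^{10})/(K^{11}K^{00}+K^{01}K^{10})}.
#' Low correlation, low double fault, low Q and high disagreement all
#' indicate a diverse pair. Zero denominators yield 0 with a `degenerate`
#' flag.
#'
#' @param k a [pair_contingency()]
#' @return a `diversity_report` list: correlation, double_fault,
#'   disagreement, q_statistic
#' @export
pairwise_diversity <- function(k) {
  stopifnot(inherits(k, "pair_contingency"))
  K11 <- as.numeric(k$K11); K10 <- as.numeric(k$K10)
  K01 <- as.numeric(k$K01); K00 <- as.numeric(k$K00)
  n <- K11 + K10 + K01 + K00
  if (n == 0) stop("input error: empty contingency", call. = FALSE)
  flags <- character(0)
  num <- K11 * K00 - K01 * K10
  cor_den <- sqrt((K11 + K10) * (K01 + K00) * (K11 + K01) * (K10 + K00))
  correlation <- if (cor_den == 0) { flags <- c(flags, "correlation"); 0 } else num / cor_den
  q_den <- K11 * K00 + K01 * K10
  q <- if (q_den == 0) { flags <- c(flags, "q_statistic"); 0 } else num / q_den
  structure(list(correlation = correlation,
                 double_fault = K00 / n,
                 disagreement = (K01 + K10) / n,
                 q_statistic = q),
            degenerate = flags, class = "diversity_report")
}

#' Ensemble-level diversity
#'
#' Unweighted mean of [pairwise_diversity()] over all unordered member
#' pairs, the aggregation used when a single diversity value is reported per
#' ensemble.
#'
#' @param members_correctness list (>= 2) of equal-length binary correctness
#'   vectors, one per member
#' @return a `diversity_report` of pair-averaged values
#' @export
ensemble_diversity <- function(members_correctness) {
  m <- length(members_correctness)
  if (m < 2L) stop("input error: need at least 2 members", call. = FALSE)
  pairs <- utils::combn(m, 2L)
  reps <- apply(pairs, 2L, function(ij) {
    unlist(pairwise_diversity(pair_contingency(
      members_correctness[[ij[1L]]], members_correctness[[ij[2L]]]))[
        c("correlation", "double_fault", "disagreement", "q_statistic")])
  })
  out <- as.list(rowMeans(reps))
  structure(out, class = "diversity_report")
}

#' Write a metric table as CSV and/or JSON
#'
#' One row per (dataset, site_type, ensemble, metric, value), the layout of
#' the usual cross-validation summary tables.
#'
#' @param rows a data.frame with at least columns `metric` and `value`
#' @param csv_path,json_path output paths (`NULL` to skip one format)
#' @return invisibly, the written paths
#' @export
write_metric_report <- function(rows, csv_path = NULL, json_path = NULL) {
  stopifnot(is.data.frame(rows), all(c("metric", "value") %in% names(rows)))
  written <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(rows, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(rows, json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, json_path)
  }
  invisible(written)
}
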