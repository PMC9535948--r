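test_that("confusion_counts tabulates the 2x2 table", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(cc[c("TP", "FP", "FN", "TN")],
                   list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  cc2 <- confusion_counts(c(1, 0), c(1, 0))
  expect_identical(c(cc2$TP, cc2$TN, cc2$FP, cc2$FN), c(1L, 1L, 0L, 0L))
  cc3 <- confusion_counts(1 - c(1, 0, 1), c(1, 0, 1))
  expect_identical(c(cc3$TP, cc3$TN), c(0L, 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), "input error")
})

test_that("metric_report matches the independent formula oracle", {
  perfect <- metric_report(confusion_counts(rep(c(1, 0), 10), rep(c(1, 0), 10)))
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$mcc, 1)
  expect_identical(perfect$error_rate, 0)

  r <- metric_report(structure(list(TP = 1L, TN = 1L, FP = 1L, FN = 1L),
                               class = "confusion_counts"))
  expect_equal(unlist(r[c("accuracy", "precision", "sensitivity",
                          "specificity", "f1")]),
               rep(0.5, 5), ignore_attr = TRUE)
  expect_identical(r$mcc, 0)

  set.seed(99)
  for (i in 1:250) {
    cts <- as.list(sample(0:500, 4, replace = TRUE))
    names(cts) <- c("TP", "TN", "FP", "FN")
    if (sum(unlist(cts)) == 0) next
    got <- metric_report(structure(cts, class = "confusion_counts"))
    want <- oracle_metrics(cts$TP, cts$TN, cts$FP, cts$FN)
    for (k in names(want)) {
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12, label = k)
    }
    expect_equal(got$accuracy + got$error_rate, 1, tolerance = 1e-15)
  }
})

test_that("zero-denominator metrics degrade to 0 with a flag", {
  r <- metric_report(confusion_counts(c(0, 0), c(1, 1)))   # no TN+FP? TP+FP=0
  expect_identical(r$precision, 0)
  expect_true("precision" %in% attr(r, "degenerate"))
  expect_true("specificity" %in% attr(r, "degenerate"))
  expect_error(metric_report(structure(list(TP = 0L, TN = 0L, FP = 0L, FN = 0L),
                                       class = "confusion_counts")),
               "input error")
})

test_that("pair_contingency counts K^ij and is swap-symmetric", {
  k <- pair_contingency(c(1, 1, 1, 0), c(1, 0, 1, 1))
  expect_identical(unlist(k[c("K11", "K10", "K01", "K00")]),
                   c(K11 = 2L, K10 = 1L, K01 = 1L, K00 = 0L))
  a <- c(1, 0, 1, 1, 0)
  expect_identical(pair_contingency(a, a)$K10, 0L)
  expect_identical(pair_contingency(a, a)$K01, 0L)
  k2 <- pair_contingency(a, 1 - a)
  expect_identical(c(k2$K11, k2$K00), c(0L, 0L))
})

test_that("pairwise_diversity matches hand enumeration and the oracle", {
  d <- pairwise_diversity(pair_contingency(c(1, 1, 1, 0), c(1, 0, 1, 1)))
  expect_identical(d$double_fault, 0)
  expect_identical(d$disagreement, 0.5)
  expect_identical(d$q_statistic, -1)
  expect_equal(d$correlation, -1 / 3, tolerance = 1e-15)

  same <- pairwise_diversity(pair_contingency(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_identical(same$q_statistic, 1)
  expect_identical(same$disagreement, 0)
  expect_identical(same$correlation, 1)

  set.seed(123)
  a <- rbinom(10000, 1, 0.5); b <- rbinom(10000, 1, 0.5)
  null <- pairwise_diversity(pair_contingency(a, b))
  expect_lt(abs(null$correlation), 0.05)
  expect_lt(abs(null$q_statistic), 0.05)

  for (i in 1:100) {
    a <- rbinom(60, 1, runif(1, 0.1, 0.9))
    b <- rbinom(60, 1, runif(1, 0.1, 0.9))
    got <- pairwise_diversity(pair_contingency(a, b))
    want <- oracle_diversity(a, b)
    for (k in c("correlation", "double_fault", "disagreement", "q_statistic")) {
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
    }
    ## swapping classifiers leaves all four metrics unchanged
    swapped <- pairwise_diversity(pair_contingency(b, a))
    expect_equal(got, swapped, ignore_attr = TRUE)
  }
})

test_that("MCC vanishes when predictions are independent of truth", {
  set.seed(7)
  truth <- rbinom(10000, 1, 0.5)
  pred <- sample(truth)                          # permuted labels
  expect_lt(abs(metric_report(confusion_counts(pred, truth))$mcc), 0.05)
})

test_that("ensemble_diversity averages over unordered pairs", {
  set.seed(31)
  members <- replicate(4, rbinom(40, 1, 0.6), simplify = FALSE)
  got <- ensemble_diversity(members)
  pairs <- utils::combn(4, 2)
  want <- rowMeans(apply(pairs, 2, function(ij) {
    o <- oracle_diversity(members[[ij[1]]], members[[ij[2]]])
    c(o$correlation, o$double_fault, o$disagreement, o$q_statistic)
  }))
  expect_equal(unlist(got[c("correlation", "double_fault", "disagreement",
                            "q_statistic")]),
               want, tolerance = 1e-12, ignore_attr = TRUE)

  two <- ensemble_diversity(members[1:2])
  direct <- pairwise_diversity(pair_contingency(members[[1]], members[[2]]))
  expect_equal(two, direct, ignore_attr = TRUE)

  same <- ensemble_diversity(rep(list(members[[1]]), 3))
  expect_identical(same$disagreement, 0)
  expect_identical(same$q_statistic, 1)
  expect_error(ensemble_diversity(members[1]), "input error")
})

test_that("metric report writers emit CSV and JSON", {
  rows <- data.frame(dataset = "synthetic", site_type = "donor",
                     ensemble = "ENS2", metric = c("accuracy", "mcc"),
                     value = c(0.95, 0.9))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rows, csv, js)
  expect_equal(utils::read.csv(csv)$value, rows$value)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$value, rows$value)
})
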