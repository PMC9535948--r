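test_that("one-hot mapping is exactly the published base -> row code", {
  ds <- splice_dataset(c("ACGT"), 1L, "donor", consensus_positions = c(3L, 4L))
  b <- encode_one_hot(ds)
  expect_equal(b[1, , ], rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                               c(0, 0, 1, 0), c(0, 0, 0, 1)),
               ignore_attr = TRUE)

  ds2 <- splice_dataset(c("AAAA", "ANGT"), c(1L, 0L), "donor",
                        consensus_positions = c(3L, 4L))
  b2 <- encode_one_hot(ds2)
  expect_true(all(b2[1, , "A"] == 1) && all(b2[1, , c("C", "G", "T")] == 0))
  expect_equal(unname(b2[2, 2, ]), c(0, 0, 0, 0))   # N -> all-zero row
  expect_equal(unname(b2[2, 1, ]), c(1, 0, 0, 0))
  expect_equal(dim(b2), c(2L, 4L, 4L))
})

test_that("encode/decode round-trips and rejects corrupted batches", {
  seqs <- random_sequences(50, 20, alphabet = c("A", "C", "G", "T", "N"),
                           seed = 7)
  ds <- splice_dataset(seqs, rep_len(0:1, 50), "acceptor",
                       consensus_positions = c(9L, 10L))
  expect_identical(decode_one_hot(encode_one_hot(ds)), ds$sequences)

  b <- encode_one_hot(ds[1:2])
  b[1, 1, ] <- c(1, 1, 0, 0)
  expect_error(decode_one_hot(b), "sum > 1")
  b[1, 1, ] <- c(0.5, 0, 0, 0)
  expect_error(decode_one_hot(b), "non-binary")
  expect_identical(decode_one_hot(array(0, c(0, 5, 4))), character(0))
})

test_that("every one-hot row over {A,C,G,T} sums to 1 in (A,C,G,T) order", {
  ds <- splice_dataset(random_sequences(30, 15, seed = 3), rep_len(0:1, 30),
                       "donor", consensus_positions = c(7L, 8L))
  b <- encode_one_hot(ds)
  expect_true(all(apply(b, c(1, 2), sum) == 1))
  expect_identical(dimnames(b)[[3]], c("A", "C", "G", "T"))
})

test_that("read_dataset handles FASTA and plain text identically", {
  din_at <- function(s) substr(s, 71, 72)
  pos <- random_sequences(2, 140, seed = 11)
  neg <- random_sequences(2, 140, seed = 12)
  substr(pos, 71, 71) <- "G"; substr(pos, 72, 72) <- "T"

  plain_p <- withr::local_tempfile(fileext = ".txt")
  plain_n <- withr::local_tempfile(fileext = ".txt")
  writeLines(tolower(pos), plain_p)            # case-insensitive input
  writeLines(neg, plain_n)
  fa_p <- withr::local_tempfile(fileext = ".fa")
  fa_n <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(rbind(paste0(">p", 1:2), pos)), fa_p)
  writeLines(c(rbind(paste0(">n", 1:2), neg)), fa_n)

  d1 <- read_dataset(plain_p, plain_n, "hs3d_140", "donor")
  d2 <- read_dataset(fa_p, fa_n, "hs3d_140", "donor")
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$labels, c(1L, 1L, 0L, 0L))
  expect_identical(d1$window_length, 140L)
  expect_identical(d1$consensus_positions, c(71L, 72L))
  expect_true(all(din_at(d1$sequences[1:2]) == "GT"))

  acc <- read_dataset(fa_p, fa_n, "hs3d_140", "acceptor")
  expect_identical(acc$consensus_positions, c(69L, 70L))
})

test_that("read_dataset enforces window length and non-empty input", {
  short <- withr::local_tempfile(fileext = ".txt")
  writeLines(random_sequences(1, 139, seed = 1), short)
  ok <- withr::local_tempfile(fileext = ".txt")
  writeLines(random_sequences(1, 140, seed = 2), ok)
  expect_error(read_dataset(short, ok, "hs3d_140", "donor"), "integrity")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_dataset(empty, ok, "hs3d_140", "donor"), "empty")
})

test_that("combined CSV dialect and generic geometry work", {
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sequence = random_sequences(4, 30, seed = 5),
                              label = c(1, 1, 0, 0)), csv, row.names = FALSE)
  ds <- read_dataset(csv, NULL, "generic", "acceptor",
                     window_length = 30, consensus_positions = c(14, 15))
  expect_identical(length(ds), 4L)
  expect_identical(ds$labels, c(1L, 1L, 0L, 0L))
})

test_that("write_dataset_fasta round-trips through read_dataset", {
  ds <- tiny_dataset(5, 20, "acceptor", cp = c(9L, 10L), seed = 21)
  pos <- withr::local_tempfile(fileext = ".fa")
  neg <- withr::local_tempfile(fileext = ".fa")
  write_dataset_fasta(ds, pos, neg)
  back <- read_dataset(pos, neg, "generic", "acceptor",
                       window_length = 20, consensus_positions = c(9, 10))
  expect_setequal(back$sequences, ds$sequences)
  expect_identical(sort(back$labels), sort(ds$labels))
})

test_that("validate_consensus flags exactly the violating records", {
  ds <- tiny_dataset(4, 12, "donor", cp = c(5L, 6L))
  expect_length(validate_consensus(ds)$violations, 0)
  seqs <- ds$sequences
  substr(seqs[3], 5, 6) <- "GA"
  ds2 <- splice_dataset(seqs, ds$labels, "donor", window_length = 12,
                        consensus_positions = c(5L, 6L))
  rep <- validate_consensus(ds2)
  expect_identical(rep$violations, 3L)
  expect_identical(rep$positive_violations, 3L)
})

test_that("subsample_balance is deterministic, exact, and validates counts", {
  ds <- tiny_dataset(10, 12)
  s1 <- subsample_balance(ds, 3, seed = 7)
  s2 <- subsample_balance(ds, 3, seed = 7)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(table(s1$labels), table(factor(c(0, 0, 0, 1, 1, 1))),
                   ignore_attr = TRUE)
  expect_length(s1, 6L)
  s3 <- subsample_balance(ds, 3, seed = 8)
  expect_false(identical(s1$sequences, s3$sequences))
  expect_error(subsample_balance(ds, 11), "insufficient data.*deficit 1")
})
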