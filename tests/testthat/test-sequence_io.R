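test_that("read_fasta normalises U to T, uppercases and preserves order", {
  tf <- write_tmp_fasta(c(">a", "ACGU", ">b", "acgt"))
  rec <- read_fasta(tf)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$sequence, c("ACGT", "ACGT"))

  tf2 <- write_tmp_fasta(c(">w1", strrep("A", 101), ">w2", strrep("C", 101)))
  rec2 <- read_fasta(tf2, label = 1)
  expect_equal(nchar(rec2$sequence), c(101L, 101L))
  expect_equal(rec2$label, c(1L, 1L))
})

test_that("read_fasta rejects bad characters, N (strict) and missing files", {
  tf <- write_tmp_fasta(c(">a", "ACXG"))
  expect_error(read_fasta(tf), "X")
  tfn <- write_tmp_fasta(c(">a", "ACNG"))
  expect_error(read_fasta(tfn), "N bases")
  expect_error(read_fasta(tempfile()), "does not exist")
})

test_that("permissive N imputation is deterministic and alphabet-clean", {
  tf <- write_tmp_fasta(c(">a", "ANNG"))
  r1 <- read_fasta(tf, n_policy = "random", seed = 4)
  r2 <- read_fasta(tf, n_policy = "random", seed = 4)
  expect_identical(r1, r2)
  expect_false(grepl("N", r1$sequence))
})

test_that("write_fasta / read_fasta round-trips records byte-exactly", {
  rec <- generate_dataset(5, 5, window_length = 31, seed = 9)
  p1 <- tempfile(fileext = ".fa")
  write_fasta(rec, p1)
  back <- read_fasta(p1)
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
  p2 <- tempfile(fileext = ".fa")
  write_fasta(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("extract_window returns the centred inclusive window", {
  expect_equal(extract_window("ACGTA", center = 2, flank = 1), "CGT")
  long <- strrep("ACGT", 100)
  w <- extract_window(long, center = 200, flank = 50)
  expect_equal(nchar(w), 101L)
  # length contract across random centres
  for (ctr in c(60, 100, 333)) {
    expect_equal(nchar(extract_window(long, ctr, 50)), 101L)
  }
})

test_that("windows overhanging either sequence end are errors", {
  s <- strrep("A", 60)
  expect_error(extract_window(s, center = 5, flank = 50), "left")
  expect_error(extract_window(s, center = 55, flank = 50), "right")
  expect_error(extract_window(s, center = 60, flank = 1), "0-based")
})

test_that("redundancy_filter applies the >= threshold greedy Hamming rule", {
  base <- random_seq(100)
  flip <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(k)
    ch[idx] <- vapply(ch[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                      character(1))
    paste(ch, collapse = "")
  }
  # identical pair collapses
  rec <- tibble::tibble(id = c("a", "b"), sequence = c(base, base))
  expect_equal(nrow(redundancy_filter(rec)), 1L)
  # 21 mismatches: identity 0.79 < 0.8, both kept
  rec2 <- tibble::tibble(id = c("a", "b"), sequence = c(base, flip(base, 21)))
  expect_equal(nrow(redundancy_filter(rec2, 0.8)), 2L)
  # 20 mismatches: identity 0.80 >= 0.8, second discarded
  rec3 <- tibble::tibble(id = c("a", "b"), sequence = c(base, flip(base, 20)))
  expect_equal(nrow(redundancy_filter(rec3, 0.8)), 1L)
})

test_that("redundancy_filter is idempotent and keeps input order", {
  set.seed(41)
  rec <- tibble::tibble(
    id = sprintf("s%02d", 1:20),
    sequence = replicate(20, random_seq(50))
  )
  kept <- redundancy_filter(rec, 0.6)
  expect_identical(redundancy_filter(kept, 0.6), kept)
  expect_identical(kept$id, sort(kept$id))
})

test_that("redundancy_filter requires equal-length windows", {
  rec <- tibble::tibble(id = c("a", "b"),
                        sequence = c("ACGTACGT", "ACGT"))
  expect_error(redundancy_filter(rec), "equal-length")
})

test_that("split_dataset yields the stratified 64/16/20 partition", {
  rec <- generate_dataset(500, 500, window_length = 21, seed = 3)
  sp <- split_dataset(rec, seed = 5)
  expect_equal(nrow(sp$train), 640L)
  expect_equal(nrow(sp$validation), 160L)
  expect_equal(nrow(sp$test), 200L)
  # stratification: both classes balanced in every subset
  for (part in sp) expect_equal(sum(part$label == 1), nrow(part) / 2)
  # disjoint and exhaustive
  all_ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_equal(sort(all_ids), sort(rec$id))
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("split_dataset is deterministic for a fixed seed", {
  rec <- generate_dataset(30, 30, window_length = 21, seed = 3)
  s1 <- split_dataset(rec, seed = 42)
  s2 <- split_dataset(rec, seed = 42)
  expect_identical(s1, s2)
  s3 <- split_dataset(rec, seed = 43)
  expect_false(identical(s1$train$id, s3$train$id))
  # train + validation fraction honours train_fraction
  expect_equal(nrow(s1$train) + nrow(s1$validation), 48L)
})

test_that("split_dataset rejects single-class input", {
  rec <- generate_dataset(10, 10, window_length = 21, seed = 3)
  expect_error(split_dataset(dplyr::filter(rec, label == 1)), "both classes")
})
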