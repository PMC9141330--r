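# Adapter detection, quality end-trimming, size partitioning

test_that("adapter detection finds the leftmost qualifying position", {
  p <- trim_params(TEST_ADAPTER)
  # exact adapter at a known offset
  expect_equal(adapter_positions(paste0("ACGTACGT", TEST_ADAPTER), p), 8L)
  # pure adapter read: detected at position 0
  expect_equal(adapter_positions(TEST_ADAPTER, p), 0L)
  # random non-adapter read: no detection
  set.seed(5)
  expect_true(is.na(adapter_positions(
    "ACCTGAGCTAGCTCGATCGAGCGATCGCCTATGCATCGATCGTACCACGGT", p)))
  # adapter occurring twice: leftmost wins
  two <- paste0("ACGTACGTACGTACGTAC", TEST_ADAPTER, "AC", TEST_ADAPTER)
  expect_equal(adapter_positions(two, p), 18L)
  # N in the read counts as a mismatch
  p0 <- trim_params(TEST_ADAPTER, max_mismatch_rate = 0)
  readN <- paste0("ACGTACGTACGTACGTAC", sub("G", "N", TEST_ADAPTER))
  expect_true(is.na(adapter_positions(readN, p0)))
})

test_that("adapter detection agrees with the exhaustive (position, overlap) scan", {
  set.seed(202)
  for (k in 1:300) {
    mo <- sample(4:8, 1)
    rate <- sample(c(0, 0.1, 0.2), 1)
    adapter <- rand_dna(1, sample(mo:15, 1))
    p <- trim_params(adapter, min_overlap = mo, max_mismatch_rate = rate)
    L <- sample(10:60, 1)
    seq <- if (runif(1) < 0.5) {
      rand_dna(1, L)                                   # background
    } else {                                           # planted adapter
      ins <- rand_dna(1, sample(0:30, 1))
      substr(paste0(ins, adapter, rand_dna(1, 30)), 1, max(L, nchar(ins) + mo))
    }
    expect_identical(adapter_positions(seq, p),
                     oracle_adapter_scan(seq, adapter, mo, rate),
                     info = sprintf("case %d: %s / %s", k, seq, adapter))
  }
})

test_that("detected inserts never retain any detected adapter overlap", {
  set.seed(203)
  p <- trim_params(TEST_ADAPTER)
  ins <- rand_dna(100, sample(18:40, 100, replace = TRUE))
  reads <- substr(paste0(ins, TEST_ADAPTER, rand_dna(100, 30)), 1, 51)
  pos <- adapter_positions(reads, p)
  expect_false(anyNA(pos))
  # the insert is strictly before the detected adapter start
  expect_true(all(pos <= nchar(ins)))
})

test_that("detect_and_trim_adapter returns the insert or NO_ADAPTER", {
  p <- trim_params(TEST_ADAPTER)
  q <- rep(40L, 8 + nchar(TEST_ADAPTER))
  out <- detect_and_trim_adapter(paste0("ACGTACGT", TEST_ADAPTER), q, p)
  expect_equal(out$status, "KEPT")
  expect_equal(out$insert, "ACGTACGT")
  expect_equal(out$insert_qualities, rep(40L, 8))
  out2 <- detect_and_trim_adapter("ACCTGAGCTAGCTCGATCGAGCGATCGCCTA",
                                  rep(40L, 31), p)
  expect_equal(out2$status, "NO_ADAPTER")
})

test_that("quality_end_trim returns the longest qualifying prefix", {
  # all high quality: unchanged
  out <- quality_end_trim("ACGT", rep(40L, 4), 30)
  expect_equal(out$sequence, "ACGT")
  # prefix means 40, 25, 30: only the length-1 prefix qualifies
  out <- quality_end_trim("ACG", c(40L, 10L, 40L), 30)
  expect_equal(out$sequence, "A")
  expect_equal(out$qualities, 40L)
  # can trim to empty
  out <- quality_end_trim("ACG", c(10L, 10L, 10L), 30)
  expect_equal(out$sequence, "")
  expect_length(out$qualities, 0L)
})

test_that("quality_end_trim matches the brute-force prefix oracle and is idempotent", {
  set.seed(204)
  for (k in 1:1000) {
    L <- sample(1:51, 1)
    q <- sample(0:45, L, replace = TRUE)
    thr <- sample(c(20, 30, 35), 1)
    s <- paste(rep("A", L), collapse = "")
    out <- quality_end_trim(s, q, thr)
    expect_equal(nchar(out$sequence), oracle_qtrim_len(q, thr))
    again <- quality_end_trim(out$sequence, out$qualities, thr)
    expect_identical(again, out)
  }
})

test_that("size partition follows the 18-40 / 41-150 bounds", {
  p <- trim_params(TEST_ADAPTER)
  expect_equal(as.character(partition_by_size(c(22L, 18L, 40L), p)),
               rep("MIR_PIRNA_18_40", 3))
  expect_equal(as.character(partition_by_size(c(41L, 100L, 150L), p)),
               rep("LONG_40_150", 3))
  expect_equal(as.character(partition_by_size(c(0L, 17L, 151L), p)),
               rep("NONE", 3))
})

test_that("process_library conserves reads and classifies per stage", {
  p <- trim_params(TEST_ADAPTER)
  hiq <- function(n) lapply(seq_len(n), function(i) rep(38L, 51L))
  set.seed(205)
  clean_ins <- rand_dna(100, sample(18:40, 100, replace = TRUE))
  clean <- substr(paste0(clean_ins, TEST_ADAPTER, rand_dna(100, 33)), 1, 51)
  reads <- make_reads(clean, hiq(100))
  out <- process_library(reads, p)
  expect_equal(out$attrition$status$KEPT, 100L)
  expect_equal(nrow(out$inserts), 100L)
  expect_equal(sort(out$inserts$sequence), sort(clean_ins))

  # mix in 20 adapter-less reads, one pure-adapter read, one low-quality
  noad <- replicate(20, {
    r <- rand_dna(1, 51)
    while (!is.na(adapter_positions(r, p))) r <- rand_dna(1, 51)
    r
  })
  pure <- substr(paste0(TEST_ADAPTER, rand_dna(1, 51)), 1, 51)
  lowq_seq <- substr(paste0(rand_dna(1, 22), TEST_ADAPTER, rand_dna(1, 33)), 1, 51)
  mix <- rbind(reads,
               make_reads(noad, hiq(20)),
               make_reads(pure, hiq(1)),
               make_reads(lowq_seq, list(c(rep(2L, 22), rep(38L, 29)))))
  out2 <- process_library(mix, p, keep_per_read = TRUE)
  st <- out2$attrition$status
  expect_equal(st$NO_ADAPTER, 20L)
  expect_equal(st$OUT_OF_SIZE, 1L)        # empty insert: size rule rejects
  expect_equal(st$EMPTY_AFTER_QTRIM, 1L)
  expect_equal(Reduce(`+`, st), nrow(mix))  # conservation
  expect_equal(sum(unlist(out2$attrition$fraction)), st$KEPT)

  # the long fraction is kept but not part of the quantified inserts
  long_ins <- rand_dna(5, 42L)
  long <- substr(paste0(long_ins, TEST_ADAPTER, rand_dna(5, 33)), 1, 51 + 12)
  out3 <- process_library(make_reads(substr(long, 1, 51), hiq(5)), p)
  expect_equal(out3$attrition$fraction$LONG_40_150, 5L)
  expect_equal(nrow(out3$inserts), 0L)
})

test_that("qtrim-first order trims before adapter detection and conserves", {
  p <- trim_params(TEST_ADAPTER)
  set.seed(206)
  ins <- rand_dna(50, sample(18:40, 50, replace = TRUE))
  reads <- make_reads(substr(paste0(ins, TEST_ADAPTER, rand_dna(50, 33)), 1, 51),
                      lapply(seq_len(50), function(i) rep(38L, 51L)))
  out <- process_library(reads, p, order = "qtrim-first")
  expect_equal(out$attrition$status$KEPT, 50L)
  # a read whose tail quality collapses loses the adapter under qtrim-first
  q <- c(rep(38L, 20), rep(2L, 31))
  one <- make_reads(reads$sequence[1], list(q))
  out_q <- process_library(one, p, order = "qtrim-first")
  expect_equal(out_q$attrition$status$NO_ADAPTER, 1L)
  out_a <- process_library(one, p, order = "adapter-first")
  expect_equal(Reduce(`+`, out_q$attrition$status), 1L)
  expect_equal(Reduce(`+`, out_a$attrition$status), 1L)
})
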