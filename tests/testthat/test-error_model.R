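test_that("PHRED conversions are exact and round-trip", {
  expect_equal(quality_to_error_prob(0L), 1)
  expect_equal(quality_to_error_prob(10L), 0.1)
  expect_equal(quality_to_error_prob(20L), 0.01)
  for (p in c(1, 0.1, 0.01, 0.001))
    expect_equal(quality_to_error_prob(error_prob_to_quality(p)), p,
                 tolerance = 1e-12)
  expect_error(quality_to_error_prob(-1L), "non-negative")
  expect_error(error_prob_to_quality(0), "\\(0, 1\\]")
})

test_that("quality distributions are estimated as per-cycle frequencies", {
  # two reads, constant quality 30 -> every cycle a point mass at 30
  r <- read_set(c("a", "b"), c("ACGT", "ACGT"),
                list(rep(30L, 4), rep(30L, 4)))
  qd <- estimate_quality_distribution(r)
  expect_identical(qd$n_cycles, 4L)
  expect_equal(unname(qd$probs[, "30"]), rep(1, 4))
  expect_equal(rowSums(qd$probs), rep(1, 4))

  # mixed scores at cycle 0 -> empirical frequencies
  r2 <- read_set(c("a", "b"), c("A", "A"), list(20L, 40L))
  qd2 <- estimate_quality_distribution(r2)
  expect_equal(unname(qd2$probs[1, c("20", "40")]), c(0.5, 0.5))

  # ragged lengths: deep cycles come from the reads that reach them
  r3 <- read_set(c("a", "b"), c("AAA", "AAAAA"),
                 list(rep(10L, 3), rep(20L, 5)))
  qd3 <- estimate_quality_distribution(r3)
  expect_equal(unname(qd3$probs[1, c("10", "20")]), c(0.5, 0.5))
  expect_equal(unname(qd3$probs[4:5, "20"]), c(1, 1))
})

test_that("quality estimation is invariant to read order and duplication", {
  set.seed(9)
  qual <- lapply(1:40, function(i) sample(10:35, sample(20:30, 1), TRUE))
  seqs <- vapply(lengths(qual), function(l) strrep("A", l), character(1))
  r <- read_set(sprintf("r%d", 1:40), seqs, qual)
  qd <- estimate_quality_distribution(r)
  perm <- sample(40)
  qd_perm <- estimate_quality_distribution(
    read_set(r$id[perm], r$seq[perm], r$qual[perm]))
  expect_equal(qd_perm, qd, tolerance = 1e-12)
  k <- 3L
  qd_dup <- estimate_quality_distribution(
    read_set(rep(r$id, k), rep(r$seq, k), rep(r$qual, k)))
  expect_equal(qd_dup, qd, tolerance = 1e-12)
})

test_that("count_error_types walks CIGAR and MD correctly", {
  mk <- function(cigar, md, seq) data.frame(
    read_id = "r", genome_id = "g", start = 0L, cigar = cigar, seq = seq,
    md = md, nm = NA_integer_, is_mapped = TRUE, flag = 0L,
    stringsAsFactors = FALSE)

  # one insertion, no mismatch
  c1 <- count_error_types(mk("3M1I3M", "6", "ACGTACG"))
  expect_identical(c(c1$ins, c1$del, c1$sub), c(1L, 0L, 0L))
  expect_true(all(c1$sub_pairs == 0))

  # one substitution: ref A at aligned offset 2, read base G
  c2 <- count_error_types(mk("7M", "2A4", "ACGTACG"))
  expect_identical(c(c2$ins, c2$del, c2$sub), c(0L, 0L, 1L))
  expect_identical(c2$sub_pairs["A", "G"], 1)
  expect_identical(sum(c2$sub_pairs), 1)

  # one deletion
  c3 <- count_error_types(mk("2M1D3M", "2^T3", "ACGTA"))
  expect_identical(c(c3$ins, c3$del, c3$sub), c(0L, 1L, 0L))

  # soft clips shift read offsets: mismatch at aligned offset 0 is read
  # base 3 (after the 3S); MD inconsistent with CIGAR must raise
  c4 <- count_error_types(mk("3S4M", "0C3", "AAAGTTT"))
  expect_identical(c4$sub_pairs["C", "G"], 1)
  expect_error(count_error_types(mk("4M", "2A4", "ACGTACG")),
               "inconsistent")
})

test_that("finalize_model normalizes counts and falls back to defaults", {
  qd <- flat_qdist()
  pairs <- matrix(0, 4, 4, dimnames = list(c("A","T","C","G"),
                                           c("A","T","C","G")))
  m <- finalize_model(list(ins = 10, del = 5, sub = 985, sub_pairs = pairs),
                      qd, "illumina")
  expect_equal(unname(m$proportions), c(0.01, 0.005, 0.985))
  expect_identical(m$quality_offset, 64L)

  # no observed errors: platform defaults
  m454 <- finalize_model(NULL, qd, "454")
  expect_equal(unname(m454$proportions), c(0.2, 0.15, 0.65))
  expect_identical(m454$quality_offset, 33L)
  expect_equal(m454$submat, default_substitution_matrix("454"))
  mill <- finalize_model(NULL, qd, "illumina")
  expect_equal(unname(mill$proportions), c(0.01, 0.005, 0.985))

  # observed substitution pairs are normalized to a joint distribution
  pairs["A", "G"] <- 30; pairs["T", "C"] <- 10
  m2 <- finalize_model(list(ins = 0, del = 0, sub = 40, sub_pairs = pairs),
                       qd, "illumina")
  expect_equal(m2$submat["A", "G"], 0.75)
  expect_equal(sum(m2$submat), 1)
})

test_that("the default 454 substitution matrix is a joint distribution", {
  m <- default_substitution_matrix("454")
  expect_equal(sum(m), 1, tolerance = 1e-3)
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))
})

test_that("error-model files round-trip bit-exactly", {
  set.seed(5)
  probs <- matrix(runif(5 * 4), 5, 4,
                  dimnames = list(NULL, c(7, 19, 30, 41)))
  probs <- probs / rowSums(probs)
  m <- error_model("454", quality_distribution(probs))
  p <- withr::local_tempfile(fileext = ".txt")
  write_error_model(m, p)
  m2 <- read_error_model(p)
  expect_identical(m2$platform, m$platform)
  expect_identical(m2$quality_offset, m$quality_offset)
  expect_identical(m2$proportions, m$proportions)
  expect_identical(m2$submat, m$submat)
  expect_identical(m2$qdist$probs, m$qdist$probs)
})

test_that("a known error model is recovered from simulated reads", {
  fx <- make_fixture(n_genomes = 2, genome_length = 30000, seed = 77)
  model <- default_error_model("illumina", n_cycles = 80)
  cfg <- sim_config(100000, length_fixed(80), seed = 88)
  reads <- simulate_reads(fx$composition, fx$db, model, cfg)

  counts <- count_error_types(oracle_alignments(reads))
  tot <- counts$ins + counts$del + counts$sub
  est <- c(counts$ins, counts$del, counts$sub) / tot
  se <- sqrt(model$proportions * (1 - model$proportions) / tot)
  expect_true(all(abs(est - model$proportions) < 3 * se + 1e-12))

  qd_est <- estimate_quality_distribution(
    read_set(reads$id, reads$seq, reads$qual))
  expect_lt(max(qdist_tv(qd_est, model$qdist)), 0.02)
})
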