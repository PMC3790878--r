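test_that("expected allocation weights abundance by genome size", {
  db <- genome_db(c(A = strrep("A", 1500), B = strrep("C", 1000)))
  comp <- community_composition(c(A = 0.4, B = 0.6))
  # 0.4 * 1500 == 0.6 * 1000: equal expected counts
  e <- expected_allocation(comp, db, 2e6)
  expect_equal(unname(e), c(1e6, 1e6))

  comp2 <- community_composition(c(A = 0.5, B = 0.5))
  db2 <- genome_db(c(A = strrep("A", 1000), B = strrep("C", 2000)))
  e2 <- expected_allocation(comp2, db2, 3e6)
  expect_equal(unname(e2), c(1e6, 2e6))
})

test_that("allocated read counts are multinomial around the expectation", {
  db <- genome_db(c(A = strrep("A", 1000), B = strrep("C", 2000)))
  comp <- community_composition(c(A = 0.5, B = 0.5))
  set.seed(55)
  n <- 300000L
  a <- allocate_reads(comp, db, n)
  expect_identical(sum(a), n)
  p <- 1 / 3
  expect_lt(abs(a[["A"]] - n * p), 4 * sqrt(n * p * (1 - p)))
  # single genome: deterministic
  one <- community_composition(c(A = 1))
  expect_identical(allocate_reads(one, db, 17L), c(A = 17L))
})

test_that("length models sample as declared", {
  expect_identical(sample_length(length_fixed(75), 10L), rep(75L, 10L))
  expect_identical(sample_length(length_explicit(193L, 1), 5L),
                   rep(193L, 5L))
  set.seed(21)
  x <- sample_length(length_normal(250, 10, min = 60, max = 400), 10000L)
  expect_lt(abs(mean(x) - 250), 3 * 10 / sqrt(10000))
  expect_true(all(x >= 60L & x <= 400L))
  expect_error(length_explicit(integer(), numeric()), "empty support")
})

test_that("extract_fragment honours coordinates and strand", {
  db <- genome_db(c(g = "ACGTACGT", h = "AACCG"))
  expect_identical(extract_fragment(db, "g", 2L, 4L, "+"), "GTAC")
  expect_identical(extract_fragment(db, "h", 0L, 5L, "-"), "CGGTT")
  expect_error(extract_fragment(db, "g", 6L, 4L, "+"), "out of bounds")
})

test_that("a near-perfect quality model injects (almost) no errors", {
  model <- error_model("454", point_mass_quality(62L, 120L))
  tmpl <- strrep("ACGT", 25)
  set.seed(2)
  clean <- vapply(1:1000, function(i) {
    r <- inject_errors(tmpl, model)
    r$sequence == tmpl
  }, logical(1))
  expect_gte(mean(clean), 0.999)
})

test_that("a forced-substitution model changes every base", {
  model <- error_model("454", point_mass_quality(0L, 120L),
                       proportions = c(0, 0, 1))
  tmpl <- strrep("ACGT", 25)
  set.seed(3)
  r <- inject_errors(tmpl, model)
  expect_identical(nchar(r$sequence), 100L)
  a <- strsplit(tmpl, "")[[1]]
  b <- strsplit(r$sequence, "")[[1]]
  expect_true(all(a != b))                 # zero-diagonal substitution matrix
  expect_identical(r$counts[["sub"]], 100L)
  expect_identical(r$qualities, rep(0L, 100L))
})

test_that("injected error types follow the 454 default proportions", {
  fx <- make_fixture(n_genomes = 1, genome_length = 30000, seed = 14)
  model <- default_error_model("454", 100)
  cfg <- sim_config(100000, length_fixed(100), seed = 15)
  reads <- simulate_reads(fx$composition, fx$db, model, cfg)
  tot <- c(ins = sum(reads$n_ins), del = sum(reads$n_del),
           sub = sum(reads$n_sub))
  n <- sum(tot)
  p0 <- c(ins = 0.2, del = 0.15, sub = 0.65)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(tot / n - p0) < 3 * se))
  # the true CIGAR/MD agree with the per-read counts
  i <- which(reads$n_del > 0)[1]
  expect_match(reads$cigar[i], "D")
  expect_match(reads$md[i], "\\^")
})

# reproduce the allocation the simulator performed under the same seed
allocate_reads_of <- function(fx, n, seed) {
  set.seed(seed)
  allocate_reads(fx$composition, fx$db, n)
}

test_that("simulation is deterministic and conserves read counts", {
  fx <- make_fixture(preset = "LC", genome_length = 5000, seed = 1)
  model <- default_error_model("illumina", 60)
  cfg <- sim_config(4000, length_fixed(60), seed = 99)
  r1 <- simulate_reads(fx$composition, fx$db, model, cfg)
  r2 <- simulate_reads(fx$composition, fx$db, model, cfg)
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, p1, 64L)
  write_fastq(r2, p2, 64L)
  expect_identical(readLines(p1), readLines(p2))    # byte-identical
  expect_identical(length(r1$id), 4000L)
  expect_identical(as.integer(table(r1$genome_id)[c("g01", "g02")]),
                   unname(allocate_reads_of(fx, 4000, 99)))
})

test_that("error-free reads are exact substrings and per-genome counts are
           binomial around the expectation", {
  fx <- make_fixture(n_genomes = 2, genome_length = 20000, seed = 8)
  cfg <- sim_config(100000, length_fixed(70), seed = 9)
  reads <- simulate_reads(fx$composition, fx$db, NULL, cfg)
  idx <- sample(length(reads$id), 200)
  ok <- vapply(idx, function(i)
    extract_fragment(fx$db, reads$genome_id[i], reads$start[i],
                     reads$end[i] - reads$start[i],
                     reads$strand[i]) == reads$seq[i], logical(1))
  expect_true(all(ok))
  n_g1 <- sum(reads$genome_id == "g01")
  expect_lt(abs(n_g1 - 50000), 4 * sqrt(100000 * 0.25))
})

test_that("emitted per-cycle qualities reproduce the model distribution", {
  fx <- make_fixture(n_genomes = 1, genome_length = 30000, seed = 22)
  model <- default_error_model("illumina", 100)
  cfg <- sim_config(100000, length_fixed(100), seed = 23)
  reads <- simulate_reads(fx$composition, fx$db, model, cfg)
  qd <- estimate_quality_distribution(
    read_set(reads$id, reads$seq, reads$qual))
  expect_lt(max(qdist_tv(qd, model$qdist)), 0.02)
})

test_that("paired mode emits inward-facing mates on the same fragment", {
  fx <- make_fixture(n_genomes = 2, genome_length = 10000, seed = 33)
  cfg <- sim_config(2000, length_fixed(60), paired = TRUE,
                    insert_mean = 250, insert_sd = 15, seed = 34)
  reads <- simulate_reads(fx$composition, fx$db, NULL, cfg)
  expect_identical(length(reads$id), 2000L)
  expect_identical(reads$mate[reads$mate], seq_along(reads$mate))
  pv <- parse_read_id(reads$id)
  m1 <- which(pv$mate == 1L)
  m2 <- reads$mate[m1]
  expect_identical(pv$serial[m1], pv$serial[m2])
  expect_identical(reads$genome_id[m1], reads$genome_id[m2])
  # mates on opposite strands, insert spans close to the configured mean
  expect_true(all(reads$strand[m1] != reads$strand[m2]))
  span <- pmax(reads$end[m1], reads$end[m2]) -
    pmin(reads$start[m1], reads$start[m2])
  expect_lt(abs(mean(span) - 250), 3)
  expect_error(sim_config(2001, length_fixed(60), paired = TRUE,
                          insert_mean = 250, insert_sd = 15), "even")
  expect_error(sim_config(2000, length_fixed(150), paired = TRUE,
                          insert_mean = 250, insert_sd = 15), "insert_mean")
})

test_that("genomes shorter than the longest read are rejected by name", {
  db <- genome_db(c(tiny = strrep("ACGT", 10)))
  comp <- community_composition(c(tiny = 1))
  cfg <- sim_config(10, length_fixed(100), seed = 1)
  expect_error(simulate_reads(comp, db, NULL, cfg), "tiny")
})
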