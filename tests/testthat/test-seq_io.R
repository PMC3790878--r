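test_that("read_fasta parses, cleans and validates records", {
  p <- write_tmp_lines(c(">g1 some description", "acgt"), ".fasta")
  db <- read_fasta(p)
  expect_s3_class(db, "genome_db")
  expect_identical(unclass(db), c(g1 = "ACGT"))
  expect_identical(genome_sizes(db), c(g1 = 4L))

  # ambiguity codes collapse to N; U maps to T
  p2 <- write_tmp_lines(c(">g1", "ACRT", ">g2", "augc"), ".fasta")
  db2 <- read_fasta(p2)
  expect_identical(unclass(db2), c(g1 = "ACNT", g2 = "ATGC"))

  p3 <- write_tmp_lines(c(">g1", "AC", ">g1", "GT"), ".fasta")
  expect_error(read_fasta(p3), "duplicate")
})

test_that("fasta round-trips through write_fasta", {
  db <- tiny_db()
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, p)
  expect_identical(unclass(read_fasta(p)), unclass(db))
})

test_that("write_fastq encodes qualities at both offsets", {
  r <- read_set("r1", "ACGTA", list(rep(20L, 5)))
  p <- withr::local_tempfile(fileext = ".fastq")
  expect_invisible(write_fastq(r, p, 33L))
  expect_identical(write_fastq(r, p, 33L), 1L)      # one record written
  expect_identical(readLines(p)[4], "55555")        # 20 + 33 = '5'
  write_fastq(r, p, 64L)
  expect_identical(readLines(p)[4], "TTTTT")        # 20 + 64 = 'T'

  # empty stream: valid empty file, count 0
  empty <- read_set(character(), character(), list())
  expect_identical(write_fastq(empty, p, 33L), 0L)
  expect_identical(read_fastq(p, 33L)$id, character())

  # unencodable quality (above the 62-score cap a read_set would enforce)
  rbad <- list(id = "r1", seq = "AC", qual = list(c(63L, 70L)))
  expect_error(write_fastq(rbad, p, 64L), "printable")
})

test_that("fastq round-trip preserves sequences and qualities exactly", {
  set.seed(1)
  n <- 25L
  lens <- sample(5:40, n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T", "N"), l, TRUE), collapse = ""),
    character(1))
  qual <- lapply(lens, function(l) sample(0:40, l, TRUE))
  r <- read_set(sprintf("r%02d", 1:n), seqs, qual)
  for (off in c(33L, 64L)) {
    p <- withr::local_tempfile(fileext = ".fastq")
    write_fastq(r, p, off)
    rt <- read_fastq(p, off)
    expect_identical(rt$id, r$id)
    expect_identical(rt$seq, r$seq)
    expect_identical(rt$qual, r$qual)
  }
})

test_that("read_sam applies SAM conventions", {
  db <- tiny_db()
  lines <- c(sam_header(db),
             sam_line("r1", pos = 11L, cigar = "5M", seq = "ACGTA"),
             sam_line("r2", flag = 4L, rname = "*", pos = 0L, cigar = "*",
                      seq = "ACGT"),
             sam_line("r3", pos = 3L, cigar = "7M", seq = "GTACGTA",
                      "NM:i:2", "MD:Z:3A6"))
  aln <- read_sam(write_tmp_lines(lines, ".sam"))
  expect_identical(nrow(aln), 3L)
  expect_identical(aln$start[1], 10L)               # 1-based POS -> 0-based
  expect_false(aln$is_mapped[2])                    # FLAG 4
  expect_identical(aln$nm[3], 2L)
  expect_identical(aln$md[3], "3A6")
  expect_identical(sum(aln$is_mapped), 2L)

  bad <- c(sam_header(db), sam_line("r1", cigar = "5M", seq = "ACGT"))
  expect_error(read_sam(write_tmp_lines(bad, ".sam")), "line 4")
})

test_that("alignments round-trip through write_sam", {
  db <- tiny_db()
  aln <- data.frame(read_id = c("r1", "r2"), genome_id = c("gA", "gB"),
                    start = c(10L, 0L), cigar = c("4M", "2M1I1M"),
                    seq = c("ACGT", "ACGT"), md = c("4", "3"),
                    nm = c(0L, 1L), is_mapped = TRUE, flag = c(0L, 16L),
                    stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, p, db = db)
  rt <- read_sam(p)
  expect_identical(rt[names(aln)], aln)
})

test_that("cigar helpers parse ops and query lengths", {
  ops <- parse_cigar("3M1I2D4M2S")
  expect_identical(ops$op, c("M", "I", "D", "M", "S"))
  expect_identical(ops$len, c(3L, 1L, 2L, 4L, 2L))
  expect_identical(cigar_query_length("3M1I2D4M2S"), 10L)
  expect_error(parse_cigar("3M1"), "malformed")
})

test_that("composition and bias tables round-trip", {
  comp <- community_composition(c(gA = 0.25, gB = 0.75))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_composition(comp, p)
  rt <- read_composition(p)
  expect_equal(as.numeric(rt), as.numeric(comp), tolerance = 1e-12)
  expect_identical(names(rt), names(comp))

  prof <- list(gA = coverage_profile("gA", 250L, 100L, c(1.1, 0.1, 2.6)),
               gB = coverage_profile("gB", 300L, 100L, c(0.1, 5.1, 0.1)))
  pb <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_profiles(prof, pb)
  rtp <- read_coverage_profiles(pb)
  expect_equal(rtp, prof, tolerance = 1e-12)
})
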