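# Shared helpers: tiny in-code fixtures, written as plain text at test time.

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A SAM line with sensible defaults; tags as extra (unnamed) strings.
sam_line <- function(qname, ..., rname = "gA", pos = 1L, cigar = "4M",
                     seq = "ACGT", flag = 0L) {
  paste(c(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L, seq, "*", ...),
        collapse = "\t")
}

sam_header <- function(db) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", names(db), genome_sizes(db)))
}

tiny_db <- function() {
  genome_db(c(gA = strrep("ACGT", 250), gB = strrep("GGCA", 250)))
}

# quality distribution concentrated on a couple of scores
flat_qdist <- function(q = 30L, n_cycles = 50L) point_mass_quality(q, n_cycles)
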