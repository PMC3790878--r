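# Readers/writers for FASTA, FASTQ, SAM and the tabular model files.
# Coordinates are 0-based, half-open everywhere inside the package; the
# only conversion happens at the SAM boundary (1-based POS).

#' Genome database
#'
#' A named set of reference sequences over the alphabet `{A,C,G,T,N}`, the
#' universe reads are simulated from and assigned to.  Each FASTA record is
#' its own sequence; multi-replicon organisms are *not* concatenated, so no
#' reads are ever simulated across artificial junctions.
#'
#' @param sequences named character vector of DNA sequences.
#' @return An object of class `genome_db` (a named character vector).
#' @examples
#' db <- genome_db(c(gA = "ACGTACGT", gB = "GGGTTTAA"))
#' genome_sizes(db)
#' @export
genome_db <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    stop("every genome must have a non-empty identifier")
  if (anyDuplicated(ids))
    stop("duplicate genome identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(sequences) == 0L))
    stop("empty sequence for genome(s): ",
         paste(ids[nchar(sequences) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  structure(sequences, class = "genome_db")
}

#' @rdname genome_db
#' @param db a `genome_db`.
#' @return `genome_sizes()`: named integer vector of sequence lengths.
#' @export
genome_sizes <- function(db) {
  stats::setNames(nchar(unclass(db)), names(db))
}

#' @export
print.genome_db <- function(x, ...) {
  sz <- genome_sizes(x)
  cat("genome_db with", length(x), "sequence(s),",
      format(sum(sz), big.mark = ","), "bp total\n")
  for (i in seq_len(min(length(x), 10L)))
    cat(sprintf("  %-20s %s bp\n", names(x)[i], format(sz[i], big.mark = ",")))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Read reference genomes from FASTA
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any remaining
#' character outside `{A,C,G,T,N}` (IUPAC ambiguity codes included) is
#' collapsed to `N`, keeping the 4-letter alphabet assumption of the
#' substitution matrix valid downstream.
#'
#' @param path path to a (multi-)FASTA file.
#' @return A [genome_db()].  Record identifiers are the first whitespace-
#'   delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty header")
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("FASTA record with empty sequence: ",
         paste(ids[empty], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genome_db(stats::setNames(seqs, ids))
}

#' Write a genome database to FASTA
#'
#' @param db a [genome_db()].
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unclass(db))
  names(x) <- names(db)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read records (sequences + qualities)
#'
#' A light container for FASTQ-style records: parallel vectors of identifiers
#' and sequences plus a list of integer PHRED quality vectors (or `NULL` for
#' quality-less data).
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of sequences.
#' @param qual list of integer vectors (one per read, PHRED scale), or `NULL`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq, qual = NULL) {
  if (length(id) != length(seq))
    stop("id and seq lengths differ")
  if (!is.null(qual)) {
    if (length(qual) != length(seq)) stop("qual and seq lengths differ")
    ok <- vapply(seq_along(seq),
                 function(i) length(qual[[i]]) == nchar(seq[[i]]), logical(1))
    if (!all(ok))
      stop("quality length != sequence length for read(s): ",
           paste(head(id[!ok], 5), collapse = ", "))
    qv <- unlist(qual, use.names = FALSE)
    if (length(qv) > 0L && (min(qv) < 0L || max(qv) > 62L))
      stop("PHRED qualities must lie in [0, 62]")
  }
  structure(list(id = as.character(id), seq = as.character(seq), qual = qual),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "read(s)",
      if (is.null(x$qual)) "(no qualities)\n" else "(with qualities)\n")
  invisible(x)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (4-line records, uncompressed or gzipped).
#' @param offset quality encoding offset, 33 or 64.
#' @return A [read_set()] with integer PHRED qualities.
#' @export
read_fastq <- function(path, offset = 33L) {
  offset <- .check_offset(offset)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ file has ", length(lines), " lines; not a multiple of 4")
  if (length(lines) == 0L)
    return(read_set(character(), character(), list()))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  if (any(substr(hdr, 1L, 1L) != "@"))
    stop("malformed FASTQ header at record ",
         which(substr(hdr, 1L, 1L) != "@")[1])
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  qstr <- lines[seq(4L, length(lines), by = 4L)]
  if (any(nchar(qstr) != nchar(seqs)))
    stop("quality string length != sequence length at record ",
         which(nchar(qstr) != nchar(seqs))[1])
  qual <- lapply(qstr, function(s) utf8ToInt(s) - offset)
  read_set(ids, seqs, qual)
}

#' Write reads as FASTQ
#'
#' Quality characters are `chr(quality + offset)`; by the platform
#' conventions used throughout the package, offset 64 goes with Illumina
#' models and 33 with 454 models (both dialects are supported on input and
#' output).
#'
#' @param reads a [read_set()] or [simulate_reads()] result; all reads must
#'   carry qualities.
#' @param path output path.
#' @param quality_offset 33 or 64.
#' @return Number of records written, invisibly.
#' @export
write_fastq <- function(reads, path, quality_offset = 33L) {
  quality_offset <- .check_offset(quality_offset)
  if (length(reads$id) == 0L) {
    writeLines(character(), path)
    return(invisible(0L))
  }
  if (is.null(reads$qual)) stop("all reads must carry qualities")
  qcodes <- lapply(reads$qual, `+`, as.integer(quality_offset))
  rng <- range(unlist(qcodes, use.names = FALSE))
  if (rng[1] < 33L || rng[2] > 126L)
    stop("quality + offset outside printable ASCII [33, 126]")
  qstr <- vapply(qcodes, function(q) rawToChar(as.raw(q)), character(1))
  out <- character(4L * length(reads$id))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$seq
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- qstr
  writeLines(out, path)
  invisible(length(reads$id))
}

.check_offset <- function(offset) {
  offset <- as.integer(offset)
  if (!offset %in% c(33L, 64L))
    stop("quality offset must be 33 or 64")
  offset
}

#' Read alignments from SAM (or BAM)
#'
#' Parses one record per alignment line (secondary alignments included);
#' unmapped records are kept with `is_mapped = FALSE`.  SAM's 1-based `POS`
#' is converted to a 0-based `start`.  BAM input requires the Rsamtools
#' package.
#'
#' @param path SAM text (extension anything but `.bam`) or BAM file.
#' @return A `data.frame` with columns `read_id`, `genome_id`, `start`
#'   (0-based), `cigar`, `seq`, `md`, `nm`, `is_mapped`, `flag`.
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(.read_bam(path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "@") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(.empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("SAM line ", lineno[which(nf < 11L)[1]], " has fewer than 11 fields")
  get <- function(k) vapply(fields, `[[`, character(1), k)
  flag <- as.integer(get(2L))
  rname <- get(3L)
  pos <- as.integer(get(4L))
  cigar <- get(6L)
  seq <- toupper(get(10L))
  is_mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  tagv <- function(prefix) {
    vapply(fields, function(f) {
      if (length(f) <= 11L) return(NA_character_)
      t <- f[12:length(f)]
      hit <- t[startsWith(t, prefix)]
      if (length(hit) == 0L) NA_character_ else sub(prefix, "", hit[1])
    }, character(1))
  }
  nm <- suppressWarnings(as.integer(tagv("NM:i:")))
  md <- tagv("MD:Z:")
  # query-consuming CIGAR length must match SEQ when both are present
  chk <- is_mapped & cigar != "*" & seq != "*"
  if (any(chk)) {
    qlen <- vapply(cigar[chk], cigar_query_length, integer(1), USE.NAMES = FALSE)
    bad <- qlen != nchar(seq[chk])
    if (any(bad))
      stop("CIGAR/sequence length mismatch at SAM line ",
           lineno[chk][which(bad)[1]])
  }
  data.frame(read_id = get(1L), genome_id = rname, start = pos - 1L,
             cigar = cigar, seq = seq, md = md, nm = nm,
             is_mapped = is_mapped, flag = flag, stringsAsFactors = FALSE)
}

.empty_alignments <- function() {
  data.frame(read_id = character(), genome_id = character(),
             start = integer(), cigar = character(), seq = character(),
             md = character(), nm = integer(), is_mapped = logical(),
             flag = integer(), stringsAsFactors = FALSE)
}

.read_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "MD"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L) return(.empty_alignments())
  data.frame(read_id = b$qname, genome_id = as.character(b$rname),
             start = ifelse(is.na(b$pos), NA_integer_, b$pos - 1L),
             cigar = ifelse(is.na(b$cigar), "*", b$cigar),
             seq = as.character(b$seq),
             md = if (is.null(b$tag$MD)) NA_character_ else b$tag$MD,
             nm = if (is.null(b$tag$NM)) NA_integer_ else b$tag$NM,
             is_mapped = bitwAnd(b$flag, 4L) == 0L & !is.na(b$rname),
             flag = b$flag, stringsAsFactors = FALSE)
}

#' Write alignments as SAM text
#'
#' Minimal single-record-per-line SAM writer used to materialize oracle or
#' fixture alignments; emits an `@SQ` header from `db` when given.
#'
#' @param aln alignment `data.frame` as returned by [read_sam()] /
#'   [oracle_alignments()].
#' @param path output path.
#' @param db optional [genome_db()] for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, db = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(db))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(db), genome_sizes(db)))
  flag <- if ("flag" %in% names(aln)) aln$flag else
    ifelse(aln$is_mapped, 0L, 4L)
  opt <- character(nrow(aln))
  has_nm <- !is.na(aln$nm)
  opt[has_nm] <- paste0("\tNM:i:", aln$nm[has_nm])
  has_md <- !is.na(aln$md)
  opt[has_md] <- paste0(opt[has_md], "\tMD:Z:", aln$md[has_md])
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                  aln$read_id, flag,
                  ifelse(aln$is_mapped, aln$genome_id, "*"),
                  ifelse(aln$is_mapped, aln$start + 1L, 0L),
                  ifelse(aln$is_mapped, 60L, 0L),
                  ifelse(aln$is_mapped, aln$cigar, "*"),
                  ifelse(is.na(aln$seq) | aln$seq == "", "*", aln$seq),
                  opt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string (e.g. `"3M1I3M"`).
#' @return A two-column data.frame: `op` (character), `len` (integer).
#' @export
parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(op = character(), len = integer()))
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_cigar
#' @return `cigar_query_length()`: number of query (read) bases the CIGAR
#'   consumes (`M/I/S/=/X` ops).
#' @export
cigar_query_length <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

#' Read / write a community composition table
#'
#' Plain TSV, `genome_id<TAB>abundance`, `#` comment lines allowed.
#'
#' @param path file path.
#' @return [read_composition()]: a [community_composition()].
#' @export
read_composition <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("genome_id", "abundance"),
                           colClasses = c("character", "numeric"))
  community_composition(stats::setNames(tab$abundance, tab$genome_id),
                        provenance = "given")
}

#' @rdname read_composition
#' @param comp a [community_composition()].
#' @export
write_composition <- function(comp, path) {
  writeLines(c("# genome_id\tabundance",
               sprintf("%s\t%.10g", names(comp), as.numeric(comp))), path)
  invisible(path)
}

#' Read / write coverage-bias profiles
#'
#' TSV with columns `genome_id`, `interval_index` (0-based), `weight`;
#' genome lengths and the interval size are carried in `#!` header lines so
#' a file round-trips to identical profiles.
#'
#' @param path file path.
#' @return [read_coverage_profiles()]: named list of [coverage_profile()]s.
#' @export
read_coverage_profiles <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#!")]
  isize <- as.integer(sub("^#!interval_size\t", "",
                          meta[startsWith(meta, "#!interval_size")]))
  glines <- meta[startsWith(meta, "#!genome\t")]
  gf <- strsplit(sub("^#!genome\t", "", glines), "\t", fixed = TRUE)
  glen <- stats::setNames(as.integer(vapply(gf, `[[`, character(1), 2L)),
                          vapply(gf, `[[`, character(1), 1L))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(body, "\t", fixed = TRUE)
  gid <- vapply(f, `[[`, character(1), 1L)
  idx <- as.integer(vapply(f, `[[`, character(1), 2L))
  w <- as.numeric(vapply(f, `[[`, character(1), 3L))
  out <- lapply(unique(gid), function(g) {
    sel <- gid == g
    coverage_profile(g, glen[[g]], interval_size = isize,
                     weights = w[sel][order(idx[sel])])
  })
  stats::setNames(out, unique(gid))
}

#' @rdname read_coverage_profiles
#' @param profiles named list of [coverage_profile()]s.
#' @export
write_coverage_profiles <- function(profiles, path) {
  hdr <- c(sprintf("#!interval_size\t%d", profiles[[1]]$interval_size),
           vapply(profiles, function(p)
             sprintf("#!genome\t%s\t%d", p$genome_id, p$genome_length),
             character(1)),
           "# genome_id\tinterval_index\tweight")
  body <- unlist(lapply(profiles, function(p)
    sprintf("%s\t%d\t%.10g", p$genome_id,
            seq_along(p$weights) - 1L, p$weights)))
  writeLines(c(hdr, body), path)
  invisible(path)
}
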