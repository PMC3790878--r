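# Platform error models: explicit per-cycle PHRED-score distributions,
# insertion/deletion/substitution proportions, and the substitution matrix.

BASES <- c("A", "T", "C", "G")

#' PHRED score / error probability conversion
#'
#' `PHRED = -10 * log10(p)`, so `p = 10^(-phred/10)`.
#'
#' @param phred non-negative PHRED score(s).
#' @return Error probability in `(0, 1]`.
#' @examples
#' quality_to_error_prob(c(0, 10, 20))  # 1, 0.1, 0.01
#' @export
quality_to_error_prob <- function(phred) {
  if (any(phred < 0)) stop("PHRED scores must be non-negative")
  10^(-phred / 10)
}

#' @rdname quality_to_error_prob
#' @param p error probability in `(0, 1]`.
#' @return `error_prob_to_quality()`: the PHRED score.
#' @export
error_prob_to_quality <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  -10 * log10(p)
}

.QMAX <- 62L  # highest representable score (offset-64 printable range)

#' Per-cycle quality-score distribution
#'
#' The full empirical histogram of PHRED scores at every sequencing cycle —
#' an explicit distribution, not a per-cycle mean, because real per-cycle
#' score distributions are skewed and multi-modal.  Cycles beyond the
#' estimation depth reuse the last estimated cycle.
#'
#' @param probs numeric matrix, one row per cycle (0-based read coordinate),
#'   columns named with the PHRED scores they represent (subset of 0..62 is
#'   fine; columns are expanded to the full 0..62 support).
#' @return Object of class `quality_distribution`: list with `n_cycles` and
#'   `probs` (n_cycles x 63 matrix, rows summing to 1).
#' @export
quality_distribution <- function(probs) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs)))
    stop("probs must have PHRED scores as column names")
  sc <- as.integer(colnames(probs))
  if (anyNA(sc) || any(sc < 0L | sc > .QMAX))
    stop("column scores must lie in 0..", .QMAX)
  full <- matrix(0, nrow = nrow(probs), ncol = .QMAX + 1L,
                 dimnames = list(NULL, 0:.QMAX))
  full[, sc + 1L] <- probs
  rs <- rowSums(full)
  if (any(abs(rs - 1) > 1e-9))
    stop("per-cycle probabilities must sum to 1 (cycle ",
         which(abs(rs - 1) > 1e-9)[1] - 1L, " sums to ",
         format(rs[which(abs(rs - 1) > 1e-9)[1]]), ")")
  if (any(full < 0)) stop("probabilities must be non-negative")
  structure(list(n_cycles = nrow(full), probs = full),
            class = "quality_distribution")
}

#' @export
print.quality_distribution <- function(x, ...) {
  mean_q <- as.numeric(x$probs %*% (0:.QMAX))
  cat("quality_distribution over", x$n_cycles, "cycle(s); mean score",
      sprintf("%.1f at cycle 0, %.1f at cycle %d\n",
              mean_q[1], mean_q[x$n_cycles], x$n_cycles - 1L))
  invisible(x)
}

#' A degenerate quality distribution (point mass)
#'
#' Every cycle emits the same score with probability 1.  Useful as a
#' near-error-free model (`q = 62`) or a forced-error model (`q = 0`).
#'
#' @param q the score.
#' @param n_cycles number of cycles.
#' @return A [quality_distribution()].
#' @export
point_mass_quality <- function(q, n_cycles = 100L) {
  m <- matrix(1, nrow = n_cycles, ncol = 1, dimnames = list(NULL, q))
  quality_distribution(m)
}

#' Estimate the per-cycle quality distribution from reads
#'
#' `dist[c][q]` is the fraction of reads covering cycle `c` whose score at
#' `c` is `q`.  With ragged read lengths, deep cycles are estimated from the
#' reads long enough to reach them; a cycle with no coverage borrows the
#' nearest earlier estimated cycle.
#'
#' @param reads a [read_set()] whose reads all carry qualities.
#' @return A [quality_distribution()].
#' @export
estimate_quality_distribution <- function(reads) {
  if (length(reads$id) == 0L || is.null(reads$qual))
    stop("quality estimation needs at least one read with qualities")
  lens <- lengths(reads$qual)
  n_cyc <- max(lens)
  q <- unlist(reads$qual, use.names = FALSE)
  cyc <- sequence(lens) - 1L
  idx <- cyc * (.QMAX + 1L) + q + 1L
  counts <- matrix(tabulate(idx, nbins = n_cyc * (.QMAX + 1L)),
                   nrow = n_cyc, ncol = .QMAX + 1L, byrow = TRUE,
                   dimnames = list(NULL, 0:.QMAX))
  cover <- rowSums(counts)
  for (c in seq_len(n_cyc)) {
    if (cover[c] > 0) counts[c, ] <- counts[c, ] / cover[c]
    else if (c > 1L) counts[c, ] <- counts[c - 1L, ]
    else stop("no read covers cycle 0")
  }
  quality_distribution(counts)
}

#' Per-cycle total-variation distance between two quality distributions
#'
#' @param a,b [quality_distribution()]s.
#' @return Numeric vector, one TV distance (`0.5 * sum |p - q|`) per cycle,
#'   over the first `min(n_cycles)` cycles.
#' @export
qdist_tv <- function(a, b) {
  n <- min(a$n_cycles, b$n_cycles)
  0.5 * rowSums(abs(a$probs[seq_len(n), , drop = FALSE] -
                    b$probs[seq_len(n), , drop = FALSE]))
}

#' Count error types from NM/MD/CIGAR alignment fields
#'
#' Insertions and deletions are the `I`/`D` CIGAR op bases; substitutions are
#' recovered by walking the MD string against the read sequence, giving the
#' (reference base -> read base) pair for each mismatch.  Soft-clipped bases
#' are not aligned evidence and are excluded.  Records without an MD tag
#' contribute indel counts only; pairs involving `N` are not attributable to
#' the 4-letter matrix and are skipped.
#'
#' @param alignments alignment `data.frame` from [read_sam()].
#' @return List with `ins`, `del`, `sub` (base counts) and `sub_pairs`
#'   (4x4 matrix, rows = reference base, cols = read base, A/T/C/G order).
#' @export
count_error_types <- function(alignments) {
  pairs <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  out <- list(ins = 0L, del = 0L, sub = 0L, sub_pairs = pairs)
  a <- alignments[alignments$is_mapped & alignments$cigar != "*", ,
                  drop = FALSE]
  if (nrow(a) == 0L) return(out)
  # indels straight off the CIGAR, vectorized over records
  itok <- regmatches(a$cigar, gregexpr("[0-9]+I", a$cigar))
  dtok <- regmatches(a$cigar, gregexpr("[0-9]+D", a$cigar))
  oplen <- function(tl) sum(as.integer(sub("[ID]", "", unlist(tl))))
  out$ins <- oplen(itok)
  out$del <- oplen(dtok)
  # substitutions need MD + SEQ; a pure-match record has MD == "<number>"
  # (no letters once deletion runs are stripped) and contributes nothing
  has_md <- !is.na(a$md) & a$seq != "*"
  md_has_sub <- grepl("[ACGTN]", gsub("\\^[ACGTN]+", "", a$md))
  for (i in which(has_md & md_has_sub)) {
    res <- .md_walk(a$cigar[i], a$md[i], a$seq[i], a$read_id[i])
    if (nrow(res) > 0L) {
      keep <- res$ref %in% BASES & res$read %in% BASES
      for (j in which(keep))
        pairs[res$ref[j], res$read[j]] <- pairs[res$ref[j], res$read[j]] + 1
    }
  }
  out$sub_pairs <- pairs
  out$sub <- as.integer(sum(pairs))
  out
}

# Walk one CIGAR/MD pair; returns the mismatch (ref, read) base pairs.
.md_walk <- function(cigar, md, seq, read_id) {
  ops <- parse_cigar(cigar)
  # read offsets (0-based) of every aligned (M/=/X) base, in order
  qpos <- 0L
  mpos <- integer(0)
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      mpos <- c(mpos, qpos + seq_len(len) - 1L)
      qpos <- qpos + len
    } else if (op %in% c("I", "S")) qpos <- qpos + len
    # D/N/H consume no query
  }
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  j <- 0L  # aligned bases consumed
  ref <- character(0); rd <- character(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      j <- j + as.integer(t)
    } else if (startsWith(t, "^")) {
      # deleted reference bases: consume neither read nor aligned positions
    } else {
      if (j >= length(mpos))
        stop("MD string inconsistent with CIGAR for read ", read_id)
      ref <- c(ref, t)
      rd <- c(rd, substr(seq, mpos[j + 1L] + 1L, mpos[j + 1L] + 1L))
      j <- j + 1L
    }
  }
  if (j != length(mpos))
    stop("MD string inconsistent with CIGAR for read ", read_id)
  data.frame(ref = ref, read = rd, stringsAsFactors = FALSE)
}

#' Platform default error-type proportions
#'
#' Defaults estimated from platform sequencing data: Illumina
#' `(ins, del, sub) = (0.01, 0.005, 0.985)`; 454 `(0.2, 0.15, 0.65)` —
#' indels dominate on 454, substitutions on Illumina.
#'
#' @param platform `"illumina"` or `"454"`.
#' @return Named numeric vector `c(ins, del, sub)`.
#' @export
default_error_proportions <- function(platform = c("illumina", "454")) {
  platform <- match.arg(platform)
  if (platform == "illumina") c(ins = 0.01, del = 0.005, sub = 0.985)
  else c(ins = 0.2, del = 0.15, sub = 0.65)
}

#' Platform default substitution matrices
#'
#' Rows are the original (reference) base, columns the substituted (read)
#' base, in A/T/C/G order; the 12 off-diagonal entries form a joint
#' distribution over substitution pairs and sum to 1.  The 454 matrix is the
#' published 454 default.  No published Illumina matrix is bundled: the
#' Illumina default is a synthetic uniform matrix (1/12 per pair) and should
#' be replaced by an estimate from data ([count_error_types()]) whenever
#' substitution evidence is available.
#'
#' @param platform `"illumina"` or `"454"`.
#' @return 4x4 numeric matrix with zero diagonal.
#' @export
default_substitution_matrix <- function(platform = c("illumina", "454")) {
  platform <- match.arg(platform)
  if (platform == "454") {
    m <- matrix(c(0,       0.06474, 0.05735, 0.12439,
                  0.05378, 0,       0.13480, 0.06577,
                  0.05298, 0.11709, 0,       0.06752,
                  0.12384, 0.06784, 0.06990, 0),
                nrow = 4, byrow = TRUE, dimnames = list(BASES, BASES))
  } else {
    m <- matrix(1 / 12, 4, 4, dimnames = list(BASES, BASES))
    diag(m) <- 0
  }
  m
}

#' Platform error model
#'
#' Bundles the per-cycle quality distribution, the error-type proportions
#' and the substitution matrix, plus the platform's FASTQ quality-encoding
#' offset (64 for Illumina, 33 for 454 by the conventions used here;
#' overridable).
#'
#' @param platform `"illumina"` or `"454"`.
#' @param qdist a [quality_distribution()].
#' @param proportions numeric `c(ins, del, sub)` summing to 1.
#' @param submat 4x4 substitution matrix (zero diagonal, off-diagonal
#'   entries summing to 1 within 1e-4); row-conditional form is derived on
#'   demand during simulation.
#' @param quality_offset 33 or 64; default follows the platform.
#' @return Object of class `error_model`.
#' @export
error_model <- function(platform = c("illumina", "454"), qdist,
                        proportions = default_error_proportions(platform),
                        submat = default_substitution_matrix(platform),
                        quality_offset = NULL) {
  platform <- match.arg(platform)
  if (is.null(quality_offset))
    quality_offset <- if (platform == "illumina") 64L else 33L
  quality_offset <- .check_offset(quality_offset)
  stopifnot(inherits(qdist, "quality_distribution"))
  proportions <- as.numeric(proportions)
  if (length(proportions) != 3L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be 3 non-negative values (ins, del, sub) summing to 1")
  submat <- as.matrix(submat)
  if (!identical(dim(submat), c(4L, 4L)) || any(diag(submat) != 0) ||
      any(submat < 0) || abs(sum(submat) - 1) > 1e-4)
    stop("submat must be 4x4, zero diagonal, off-diagonal sum 1 (within 1e-4)")
  dimnames(submat) <- list(BASES, BASES)
  structure(list(platform = platform, quality_offset = quality_offset,
                 qdist = qdist,
                 proportions = stats::setNames(proportions,
                                               c("ins", "del", "sub")),
                 submat = submat),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("error_model:", x$platform, "(offset", paste0(x$quality_offset, ");"),
      x$qdist$n_cycles, "cycles\n  proportions ins/del/sub:",
      paste(signif(x$proportions, 4), collapse = " / "), "\n")
  invisible(x)
}

#' Build an error model from estimated counts
#'
#' Proportions are the normalized observed counts when any error was
#' observed, else the platform defaults; likewise the substitution matrix is
#' the normalized observed pair matrix when any substitution was observed,
#' else the platform default.
#'
#' @param counts result of [count_error_types()] (or `NULL` for defaults).
#' @param qdist a [quality_distribution()].
#' @param platform `"illumina"` or `"454"`.
#' @param quality_offset optional override of the platform offset.
#' @return An [error_model()].
#' @export
finalize_model <- function(counts, qdist, platform = c("illumina", "454"),
                           quality_offset = NULL) {
  platform <- match.arg(platform)
  if (is.null(counts))
    counts <- list(ins = 0, del = 0, sub = 0,
                   sub_pairs = matrix(0, 4, 4, dimnames = list(BASES, BASES)))
  total <- counts$ins + counts$del + counts$sub
  props <- if (total > 0)
    c(ins = counts$ins, del = counts$del, sub = counts$sub) / total
  else default_error_proportions(platform)
  submat <- if (sum(counts$sub_pairs) > 0)
    counts$sub_pairs / sum(counts$sub_pairs)
  else default_substitution_matrix(platform)
  error_model(platform, qdist, proportions = props, submat = submat,
              quality_offset = quality_offset)
}

#' Estimate a full error model from FASTQ + SAM files
#'
#' The per-cycle quality distribution comes from the FASTQ qualities, the
#' error-type proportions and substitution matrix from the alignment
#' NM/MD/CIGAR fields.
#'
#' @param fastq path to the FASTQ file (or a [read_set()]).
#' @param sam path to the SAM/BAM file (or an alignment `data.frame`).
#' @param platform `"illumina"` or `"454"`.
#' @param quality_offset FASTQ offset of the *input* file; defaults to the
#'   platform convention (64 Illumina, 33 454).
#' @return An [error_model()].
#' @export
estimate_error_model <- function(fastq, sam, platform = c("illumina", "454"),
                                 quality_offset = NULL) {
  platform <- match.arg(platform)
  off <- if (is.null(quality_offset)) {
    if (platform == "illumina") 64L else 33L
  } else .check_offset(quality_offset)
  reads <- if (is.character(fastq)) read_fastq(fastq, offset = off) else fastq
  aln <- if (is.character(sam)) read_sam(sam) else sam
  finalize_model(count_error_types(aln),
                 estimate_quality_distribution(reads),
                 platform, quality_offset = off)
}

#' A complete synthetic default error model
#'
#' For simulations with no sequencing data to estimate from: platform
#' default proportions and substitution matrix, plus a synthetic per-cycle
#' quality distribution whose mean score decays linearly along the read
#' (36 at cycle 0 to 22 at the last cycle for Illumina, 32 to 24 for 454)
#' with a +-3 triangular spread — a caricature of the 3'-ward quality decay
#' seen on both platforms, not an estimate from any dataset.
#'
#' @param platform `"illumina"` or `"454"`.
#' @param n_cycles number of cycles the model covers.
#' @return An [error_model()].
#' @export
default_error_model <- function(platform = c("illumina", "454"),
                                n_cycles = 100L) {
  platform <- match.arg(platform)
  mu <- if (platform == "illumina")
    seq(36, 22, length.out = n_cycles) else seq(32, 24, length.out = n_cycles)
  spread <- -3:3
  wt <- 4 - abs(spread)          # triangular weights
  wt <- wt / sum(wt)
  probs <- matrix(0, n_cycles, .QMAX + 1L, dimnames = list(NULL, 0:.QMAX))
  for (c in seq_len(n_cycles)) {
    sc <- pmin(pmax(round(mu[c]) + spread, 0L), .QMAX)
    for (k in seq_along(sc))
      probs[c, sc[k] + 1L] <- probs[c, sc[k] + 1L] + wt[k]
  }
  error_model(platform, quality_distribution(probs))
}

#' Write / read an error model as a human-diffable text file
#'
#' Sectioned text (`[meta]`, `[proportions]`, `[submatrix]`, `[quality]`)
#' with full-precision numbers, so a model round-trips bit-exactly.
#'
#' @param model an [error_model()].
#' @param path file path.
#' @return `write_error_model()`: `path` invisibly;
#'   `read_error_model()`: the [error_model()].
#' @export
write_error_model <- function(model, path) {
  num <- function(x) format(x, digits = 17)
  lines <- c("[meta]",
             paste0("platform\t", model$platform),
             paste0("offset\t", model$quality_offset),
             "[proportions]",
             paste0(c("ins", "del", "sub"), "\t", num(model$proportions)),
             "[submatrix]",
             vapply(BASES, function(b)
               paste(c(b, num(model$submat[b, ])), collapse = "\t"),
               character(1)),
             "[quality]")
  for (c in seq_len(model$qdist$n_cycles)) {
    p <- model$qdist$probs[c, ]
    nz <- which(p > 0)
    lines <- c(lines, paste(c(c - 1L, paste0(nz - 1L, ":", num(p[nz]))),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  lines <- readLines(path)
  sec <- cumsum(startsWith(lines, "["))
  secname <- sub("\\]$", "", sub("^\\[", "", lines[startsWith(lines, "[")]))
  grab <- function(name) {
    k <- which(secname == name)
    lines[sec == k & !startsWith(lines, "[")]
  }
  meta <- strsplit(grab("meta"), "\t", fixed = TRUE)
  meta <- stats::setNames(vapply(meta, `[[`, character(1), 2L),
                          vapply(meta, `[[`, character(1), 1L))
  props <- strsplit(grab("proportions"), "\t", fixed = TRUE)
  props <- stats::setNames(as.numeric(vapply(props, `[[`, character(1), 2L)),
                           vapply(props, `[[`, character(1), 1L))
  sm <- strsplit(grab("submatrix"), "\t", fixed = TRUE)
  submat <- do.call(rbind, lapply(sm, function(f) as.numeric(f[-1])))
  dimnames(submat) <- list(vapply(sm, `[[`, character(1), 1L), BASES)
  submat <- submat[BASES, ]
  ql <- strsplit(grab("quality"), "\t", fixed = TRUE)
  n_cyc <- length(ql)
  probs <- matrix(0, n_cyc, .QMAX + 1L, dimnames = list(NULL, 0:.QMAX))
  for (f in ql) {
    cyc <- as.integer(f[1]) + 1L
    kv <- strsplit(f[-1], ":", fixed = TRUE)
    probs[cyc, as.integer(vapply(kv, `[[`, character(1), 1L)) + 1L] <-
      as.numeric(vapply(kv, `[[`, character(1), 2L))
  }
  error_model(meta[["platform"]], quality_distribution(probs),
              proportions = props[c("ins", "del", "sub")], submat = submat,
              quality_offset = as.integer(meta[["offset"]]))
}
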