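# Community-composition estimation from read-to-genome alignments:
# unique counts first, then size-weighted sharing of multi-mapped reads.

#' Community composition
#'
#' Genome -> relative abundance, normalized to sum 1.
#'
#' @param x named non-negative numeric vector of abundances.
#' @param provenance `"given"` or `"estimated"`.
#' @param normalize divide by the total (default); with `normalize = FALSE`
#'   the input must already sum to 1 within `1e-9`.
#' @return Object of class `community_composition`: a named numeric vector
#'   with a `provenance` attribute.
#' @export
community_composition <- function(x, provenance = c("given", "estimated"),
                                  normalize = TRUE) {
  provenance <- match.arg(provenance)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("abundances must be named by genome_id")
  if (any(x < 0) || any(!is.finite(x)))
    stop("abundances must be finite and non-negative")
  s <- sum(x)
  if (s <= 0) stop("total abundance must be positive")
  if (normalize) x <- x / s
  else if (abs(s - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", format(s), ")")
  structure(as.numeric(x), names = names(x), provenance = provenance,
            class = "community_composition")
}

#' @export
print.community_composition <- function(x, ...) {
  cat("community_composition (", attr(x, "provenance"), ") over ",
      length(x), " genome(s)\n", sep = "")
  print(stats::setNames(round(as.numeric(x), 5), names(x)))
  invisible(x)
}

#' Group alignment hits by read
#'
#' Collapses an alignment table to one row per (read, genome) pair: a read
#' hitting one genome at several positions still counts as a unique hit to
#' that genome.  Reads with no mapped record are dropped.
#'
#' @param alignments alignment `data.frame` from [read_sam()].
#' @return `data.frame` with columns `read_id`, `genome_id` (distinct pairs)
#'   — the "hit sets" consumed by [assign_reads()].
#' @export
group_hits <- function(alignments) {
  m <- alignments[alignments$is_mapped,
                  c("read_id", "genome_id"), drop = FALSE]
  m <- unique(m[order(m$read_id, m$genome_id), , drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Assign reads to genomes with size-weighted sharing
#'
#' Two-pass procedure.  Pass 1: every read mapping to a single genome adds 1
#' to that genome.  Pass 2: a read mapping to `n` genomes distributes total
#' weight 1 across them proportionally to `m_i / s_i`, where `m_i` is the
#' genome's pass-1 unique count plus the pseudo-count and `s_i` its size in
#' bases — i.e. a reads-per-base prior, so large genomes do not soak up
#' shared reads merely by being large.  Fixing `m_i` at the pass-1 counts
#' makes the result independent of read order.
#'
#' @param hits distinct (read_id, genome_id) pairs from [group_hits()].
#' @param db the companion [genome_db()].
#' @param pseudo_count per-genome pseudo-count (default 0.001) that breaks
#'   0/0 weights when none of a read's genomes has unique support.
#' @return Object of class `read_assignment_counts`: list with `counts`
#'   (named numeric over all genomes in `db`, each `>= pseudo_count`),
#'   `pseudo_count`, `n_reads`, `n_unique`, `n_multi`.
#' @examples
#' db <- genome_db(c(gA = strrep("A", 1000), gB = strrep("C", 1000)))
#' hits <- data.frame(
#'   read_id = c(sprintf("u%d", 1:10), "m1", "m1"),
#'   genome_id = c(rep("gA", 8), rep("gB", 2), "gA", "gB"))
#' assign_reads(hits, db)$counts
#' @export
assign_reads <- function(hits, db, pseudo_count = 0.001) {
  unknown <- setdiff(unique(hits$genome_id), names(db))
  if (length(unknown) > 0)
    stop("genome(s) absent from the database: ",
         paste(unknown, collapse = ", "))
  sizes <- genome_sizes(db)
  counts <- stats::setNames(rep(pseudo_count, length(db)), names(db))
  if (nrow(hits) == 0L)
    return(structure(list(counts = counts, pseudo_count = pseudo_count,
                          n_reads = 0L, n_unique = 0L, n_multi = 0L),
                     class = "read_assignment_counts"))
  dt <- data.table::as.data.table(hits)
  dt[, n_genomes := .N, by = read_id]
  # pass 1: unique reads
  uni <- dt[n_genomes == 1L, .N, by = genome_id]
  m <- stats::setNames(rep(0, length(db)), names(db))
  m[uni$genome_id] <- uni$N
  counts <- counts + m          # pseudo + unique
  m_prior <- m + pseudo_count   # the m_i entering the weights
  # pass 2: multi-mapped reads share weight ~ m_i / s_i
  multi <- dt[n_genomes > 1L]
  if (nrow(multi) > 0L) {
    multi[, w := m_prior[genome_id] / sizes[genome_id]]
    multi[, w := w / sum(w), by = read_id]
    add <- multi[, .(w = sum(w)), by = genome_id]
    counts[add$genome_id] <- counts[add$genome_id] + add$w
  }
  n_unique <- dt[n_genomes == 1L, data.table::uniqueN(read_id)]
  n_multi <- dt[n_genomes > 1L, data.table::uniqueN(read_id)]
  structure(list(counts = counts, pseudo_count = pseudo_count,
                 n_reads = n_unique + n_multi,
                 n_unique = n_unique, n_multi = n_multi),
            class = "read_assignment_counts")
}

#' @export
print.read_assignment_counts <- function(x, ...) {
  cat("read_assignment_counts:", x$n_reads, "read(s) over",
      length(x$counts), "genome(s) (", x$n_unique, "unique,",
      x$n_multi, "multi-mapped )\n")
  invisible(x)
}

#' Filter candidate genomes and normalize to a composition
#'
#' Genomes whose weighted read count exceeds `min_reads` (strictly) enter the
#' candidate list; their counts are renormalized to relative abundances.
#'
#' @param counts a `read_assignment_counts` (or its `counts` vector).
#' @param min_reads candidate threshold (default 10).
#' @return A [community_composition()] with provenance `"estimated"`.
#' @export
candidate_filter <- function(counts, min_reads = 10) {
  if (inherits(counts, "read_assignment_counts")) counts <- counts$counts
  if (length(counts) == 0L) stop("empty count vector")
  keep <- counts > min_reads
  if (!any(keep))
    stop("no genome exceeds the candidate threshold (", min_reads,
         " reads); lower `min_reads`")
  community_composition(counts[keep], provenance = "estimated")
}

#' Estimate a community composition from alignments
#'
#' Convenience wrapper: [read_sam()] (if given a path) -> [group_hits()] ->
#' [assign_reads()] -> [candidate_filter()].
#'
#' @param alignments alignment `data.frame` or path to a SAM/BAM file.
#' @param db a [genome_db()] or path to a FASTA file.
#' @param pseudo_count per-genome pseudo-count (default 0.001).
#' @param min_reads candidate threshold (default 10).
#' @return A [community_composition()] with provenance `"estimated"`.
#' @export
estimate_composition <- function(alignments, db, pseudo_count = 0.001,
                                 min_reads = 10) {
  if (is.character(alignments)) alignments <- read_sam(alignments)
  if (is.character(db) && !inherits(db, "genome_db")) db <- read_fasta(db)
  candidate_filter(assign_reads(group_hits(alignments), db, pseudo_count),
                   min_reads = min_reads)
}

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c("n_genomes", "read_id", "genome_id", "w", "N"))
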