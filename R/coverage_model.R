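# Coverage bias: per-genome read-start counts in fixed-width intervals,
# used as sampling weights during simulation.

#' Coverage-bias profile
#'
#' Per-interval sampling weights for one genome: the genome is divided into
#' `ceil(size / interval_size)` intervals (default 100 bp) and each weight is
#' a read count plus a pseudo-count floor, so no interval is ever
#' unsampleable.  A profile is keyed to the genome it was estimated from;
#' applying it to a genome of a different length is an error, not a rescale.
#'
#' @param genome_id genome the profile belongs to.
#' @param genome_length genome length in bases.
#' @param interval_size interval width in bases (default 100).
#' @param weights per-interval weights; default all-pseudo (uniform).
#' @param pseudo_count the weight floor (default 0.1).
#' @return Object of class `coverage_profile`.
#' @export
coverage_profile <- function(genome_id, genome_length, interval_size = 100L,
                             weights = NULL, pseudo_count = 0.1) {
  genome_length <- as.integer(genome_length)
  interval_size <- as.integer(interval_size)
  if (genome_length < 1L || interval_size < 1L)
    stop("genome_length and interval_size must be positive")
  n_int <- ceiling(genome_length / interval_size)
  if (is.null(weights)) weights <- rep(pseudo_count, n_int)
  if (length(weights) != n_int)
    stop("expected ", n_int, " interval weights, got ", length(weights))
  if (any(weights < pseudo_count))
    stop("all weights must be >= the pseudo-count (", pseudo_count, ")")
  structure(list(genome_id = genome_id, genome_length = genome_length,
                 interval_size = interval_size, weights = as.numeric(weights),
                 pseudo_count = pseudo_count),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile for", x$genome_id, ":", length(x$weights),
      "intervals of", x$interval_size, "bp; weight range",
      paste(signif(range(x$weights), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Estimate coverage-bias profiles from alignments
#'
#' Each mapped read adds 1 count to exactly one interval — the one containing
#' its 0-based leftmost start coordinate — on top of a pseudo-count floor in
#' every interval.  Every genome in `db` gets a profile (all-pseudo when
#' unhit).
#'
#' @param alignments alignment `data.frame` from [read_sam()].
#' @param db a [genome_db()].
#' @param interval_size interval width in bases (default 100).
#' @param pseudo_count per-interval pseudo-count (default 0.1).
#' @return Named list of [coverage_profile()]s, one per genome in `db`.
#' @export
estimate_coverage <- function(alignments, db, interval_size = 100L,
                              pseudo_count = 0.1) {
  m <- alignments[alignments$is_mapped, , drop = FALSE]
  unknown <- setdiff(unique(m$genome_id), names(db))
  if (length(unknown) > 0)
    stop("alignment(s) to genome(s) absent from the database: ",
         paste(unknown, collapse = ", "))
  sizes <- genome_sizes(db)
  bad <- m$start < 0L | m$start >= sizes[m$genome_id]
  if (any(bad))
    stop("alignment start outside genome bounds for read ",
         m$read_id[which(bad)[1]])
  out <- lapply(names(db), function(g) {
    n_int <- ceiling(sizes[[g]] / interval_size)
    starts <- m$start[m$genome_id == g]
    cnt <- tabulate(starts %/% interval_size + 1L, nbins = n_int)
    coverage_profile(g, sizes[[g]], interval_size = interval_size,
                     weights = cnt + pseudo_count,
                     pseudo_count = pseudo_count)
  })
  stats::setNames(out, names(db))
}

#' Sample read start positions from a coverage profile
#'
#' An interval is drawn with probability proportional to its weight, the
#' start is uniform within the interval, and the start is clamped so
#' `start + read_length <= genome_length` (clamping, not wrapping: genomes
#' are treated as linear, which slightly over-weights the last valid window
#' for intervals near the 3' end).
#'
#' @param profile a [coverage_profile()].
#' @param read_length length of the read to be placed.
#' @param n number of draws.
#' @return Integer vector of `n` 0-based start coordinates.
#' @export
sample_position <- function(profile, read_length, n = 1L) {
  L <- profile$genome_length
  if (read_length > L)
    stop("read length ", read_length, " exceeds genome length ", L)
  iv <- sample.int(length(profile$weights), size = n, replace = TRUE,
                   prob = profile$weights)
  offs <- floor(runif(n, 0, profile$interval_size))
  start <- (iv - 1L) * profile$interval_size + as.integer(offs)
  pmin(start, L - as.integer(read_length))
}
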