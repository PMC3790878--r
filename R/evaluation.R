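# Fidelity metrics (Bray-Curtis, coverage comparison) and the synthetic
# fixture generator that makes the whole pipeline testable offline.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' Both vectors are first normalized to proportions (all the comparisons the
#' package makes — community compositions, error-proportion triples,
#' per-interval mean read counts — are proportional quantities; pass
#' `normalize = FALSE` for an explicit raw-count comparison), then
#' `D = sum(|x - y|) / sum(x + y)`.  `D` is 0 iff the vectors are
#' proportionally identical and 1 iff their supports are disjoint; on
#' pre-normalized input it equals `0.5 * sum(|x - y|)`.
#'
#' @param x,y non-negative numeric vectors of equal length; if both are
#'   named, `y` is aligned to `x`'s names.
#' @param normalize normalize each vector to sum 1 first (default).
#' @return The dissimilarity, in `[0, 1]`.
#' @examples
#' bc_distance(c(0.00498, 0.00985, 0.98518), c(0.00489, 0.00997, 0.98514))
#' @export
bc_distance <- function(x, y, normalize = TRUE) {
  if (length(x) != length(y))
    stop("vectors have different lengths (", length(x), " vs ", length(y), ")")
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      stop("vectors have different label sets")
    y <- y[names(x)]
  }
  if (any(x < 0) || any(y < 0) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite and non-negative")
  if (sum(x) <= 0 || sum(y) <= 0)
    stop("inputs must each have at least one positive entry")
  if (normalize) {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  sum(abs(x - y)) / sum(x + y)
}

#' Compare two coverage profiles
#'
#' Bray-Curtis distance (on normalized weights) and the Pearson correlation
#' (on raw weights — normalization cancels under Pearson) between the
#' per-interval weight vectors of two profiles of the same genome,
#' optionally truncated to the first `first_n` intervals.
#'
#' @param a,b [coverage_profile()]s with identical `genome_id`,
#'   `genome_length` and `interval_size`.
#' @param first_n optional number of leading intervals to compare.
#' @return Named list: `bc`, `pearson_r`.
#' @export
coverage_compare <- function(a, b, first_n = NULL) {
  if (!identical(a$genome_id, b$genome_id) ||
      a$genome_length != b$genome_length ||
      a$interval_size != b$interval_size)
    stop("profiles must describe the same genome at the same interval size")
  wa <- a$weights
  wb <- b$weights
  if (!is.null(first_n)) {
    if (first_n > length(wa))
      stop("first_n exceeds the interval count (", length(wa), ")")
    wa <- wa[seq_len(first_n)]
    wb <- wb[seq_len(first_n)]
  }
  list(bc = bc_distance(wa, wb), pearson_r = cor(wa, wb))
}

.FIXTURE_PRESETS <- list(
  # low complexity: two species, one dominant
  LC = c(0.9, 0.1),
  # medium complexity: nine species in five abundance levels, two dominant
  MC = c(0.28, 0.28, 0.12, 0.12, 0.06, 0.06, 0.03, 0.03, 0.02),
  # high complexity: eleven species, equal abundance
  HC = rep(1 / 11, 11)
)

#' Generate a synthetic benchmark community
#'
#' Builds i.i.d. random genomes at a requested GC content together with a
#' community composition and (optionally) sinusoidal coverage-bias profiles,
#' standing in for downloadable benchmark data in every test.  Three presets
#' mirror the classic benchmark complexities: `LC` (2 genomes, one dominant,
#' 0.9/0.1), `MC` (9 genomes in 5 abundance levels with two dominant
#' genomes) and `HC` (11 genomes at equal abundance).  Deterministic per
#' seed.
#'
#' @param preset `"LC"`, `"MC"`, `"HC"`, or `NULL` to use `n_genomes` equal
#'   abundances.
#' @param n_genomes number of genomes when no preset is given.
#' @param genome_length length of every genome (>= 1000 bp).
#' @param gc GC fraction of the i.i.d. base composition.
#' @param seed RNG seed.
#' @param bias also build sinusoidal coverage profiles (period 20 intervals,
#'   weights `1 + 0.8 sin`) for bias-recovery tests?
#' @param interval_size interval width of the bias profiles.
#' @return List with `db` ([genome_db()]), `composition`
#'   ([community_composition()]), and `profiles` (named list of
#'   [coverage_profile()]s, or `NULL`).
#' @export
make_fixture <- function(preset = NULL, n_genomes = NULL,
                         genome_length = 100000L, gc = 0.5, seed = 1L,
                         bias = FALSE, interval_size = 100L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(.FIXTURE_PRESETS))
    ab <- .FIXTURE_PRESETS[[preset]]
  } else {
    if (is.null(n_genomes) || n_genomes < 1L)
      stop("give a preset or n_genomes >= 1")
    ab <- rep(1 / n_genomes, n_genomes)
  }
  genome_length <- as.integer(genome_length)
  if (genome_length < 1000L) stop("genome_length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ids <- sprintf("g%02d", seq_along(ab))
  seqs <- vapply(ids, function(i)
    paste(sample(names(p), genome_length, replace = TRUE, prob = p),
          collapse = ""), character(1))
  db <- genome_db(stats::setNames(seqs, ids))
  comp <- community_composition(stats::setNames(ab, ids))
  profiles <- NULL
  if (bias) {
    n_int <- ceiling(genome_length / interval_size)
    profiles <- stats::setNames(lapply(ids, function(g) {
      w <- 1 + 0.8 * sin(2 * pi * seq_len(n_int) / 20)
      coverage_profile(g, genome_length, interval_size = interval_size,
                       weights = pmax(w, 0.1))
    }), ids)
  }
  list(db = db, composition = comp, profiles = profiles)
}

#' Oracle alignments from simulated-read provenance
#'
#' Rebuilds the true alignment of every simulated read from the provenance
#' the simulator recorded, replacing an external mapper in closed-loop
#' tests.  Reads that carry injected errors get their true CIGAR/MD/NM (as
#' injected, in read orientation against the oriented template, with the
#' strand folded into the recorded coordinates); error-free reads get a
#' perfect-match all-M alignment.  These records are sufficient for
#' composition, error-model and coverage re-estimation, though not
#' reference-strand SAM for a genome browser.
#'
#' @param reads a `simulated_reads` object from [simulate_reads()].
#' @return Alignment `data.frame` in the [read_sam()] layout.
#' @export
oracle_alignments <- function(reads) {
  if (!inherits(reads, "simulated_reads"))
    stop("oracle alignments need the provenance carried by simulate_reads()")
  n <- length(reads$id)
  data.frame(read_id = reads$id, genome_id = reads$genome_id,
             start = reads$start, cigar = reads$cigar, seq = reads$seq,
             md = reads$md, nm = reads$n_ins + reads$n_del + reads$n_sub,
             is_mapped = rep(TRUE, n),
             flag = ifelse(reads$strand == "-", 16L, 0L),
             stringsAsFactors = FALSE)
}

#' Parse provenance from simulated-read identifiers
#'
#' Identifiers have the form `SIM|genome|start|end|strand|serial[/1|/2]`.
#'
#' @param id character vector of read identifiers.
#' @return `data.frame` with `genome_id`, `start`, `end`, `strand`, `serial`,
#'   `mate` (1, 2 or NA).
#' @export
parse_read_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  if (any(lengths(parts) != 6L) || any(vapply(parts, `[[`, character(1), 1L)
                                       != "SIM"))
    stop("identifier(s) without SIM provenance: ",
         paste(head(id[lengths(parts) != 6L |
                         vapply(parts, `[[`, character(1), 1L) != "SIM"], 3),
               collapse = ", "))
  tailf <- vapply(parts, `[[`, character(1), 6L)
  mate <- ifelse(grepl("/1$", tailf), 1L,
                 ifelse(grepl("/2$", tailf), 2L, NA_integer_))
  data.frame(genome_id = vapply(parts, `[[`, character(1), 2L),
             start = as.integer(vapply(parts, `[[`, character(1), 3L)),
             end = as.integer(vapply(parts, `[[`, character(1), 4L)),
             strand = vapply(parts, `[[`, character(1), 5L),
             serial = as.integer(sub("/[12]$", "", tailf)),
             mate = mate, stringsAsFactors = FALSE)
}

#' Exact-substring self-mapping rates
#'
#' Locates each read (or its reverse complement) by exact substring search
#' in every genome of the database and reports how many reads map back
#' uniquely to their genome of origin, to several genomes, or to none — the
#' desk-scale analogue of mapping simulated reads back with an external
#' aligner.  Reads must share one length (exact search via a PDict).
#'
#' @param reads a `simulated_reads` object (constant read length).
#' @param db the [genome_db()] the reads were simulated from.
#' @return Named list of percentages: `unique`, `multi`, `none`.
#' @export
self_mapping_rates <- function(reads, db) {
  w <- unique(nchar(reads$seq))
  if (length(w) != 1L)
    stop("exact self-mapping needs a constant read length")
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$seq))
  subj <- Biostrings::DNAStringSet(c(unclass(db),
                                     reverse_complement(unclass(db))))
  hits <- Biostrings::vcountPDict(pd, subj)      # reads x subjects
  ng <- length(db)
  hit_g <- (hits[, seq_len(ng), drop = FALSE] +
            hits[, ng + seq_len(ng), drop = FALSE]) > 0
  n_hit <- rowSums(hit_g)
  origin <- match(reads$genome_id, names(db))
  to_origin <- hit_g[cbind(seq_along(origin), origin)]
  n <- length(reads$id)
  list(unique = 100 * sum(n_hit == 1L & to_origin) / n,
       multi = 100 * sum(n_hit > 1L) / n,
       none = 100 * sum(n_hit == 0L) / n)
}

#' Model-implied expected errors per read
#'
#' Closed form of the injection procedure: at each cycle the per-attempt
#' error probability is `p(q)` with `q` drawn from the cycle's score
#' distribution, and a deletion re-attempts the cycle, so the expected
#' number of injected errors per emitted base is
#' `E_q[ p(q) / (1 - p(q) * p_del) ]`.  Summed over the first `read_length`
#' cycles this gives the expected injected error count per read.
#'
#' @param model an [error_model()].
#' @param read_length read length in cycles.
#' @return Expected number of injected errors per read.
#' @export
expected_errors_per_read <- function(model, read_length) {
  probs <- model$qdist$probs
  pd <- model$proportions[["del"]]
  p <- quality_to_error_prob(as.integer(colnames(probs)))
  per_cycle <- as.numeric(probs %*% (p / (1 - p * pd)))
  cyc <- pmin(seq_len(read_length), model$qdist$n_cycles)
  sum(per_cycle[cyc])
}
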