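# Read simulation: multinomial allocation of reads to genomes, position /
# length / strand sampling, quality-driven error injection, FASTQ output.

#' Read-length models
#'
#' Three kinds of length model: a fixed length, a rounded normal clamped to
#' `[min, max]`, or an explicit (arbitrary empirical) length distribution —
#' 454 read-length histograms in particular are neither fixed nor normal,
#' which is what the explicit kind is for.
#'
#' @param length fixed read length.
#' @return An object of class `length_model`.
#' @export
length_fixed <- function(length) {
  length <- as.integer(length)
  if (length < 1L) stop("read length must be >= 1")
  structure(list(kind = "fixed", length = length), class = "length_model")
}

#' @rdname length_fixed
#' @param mean,sd normal parameters.
#' @param min,max clamp bounds (both >= 1).
#' @export
length_normal <- function(mean, sd, min = 1L, max = Inf) {
  if (min < 1L) stop("minimum length must be >= 1")
  if (max < min) stop("max < min")
  structure(list(kind = "normal", mean = mean, sd = sd,
                 min = as.integer(min), max = max),
            class = "length_model")
}

#' @rdname length_fixed
#' @param lengths support of the explicit distribution.
#' @param probs probabilities (normalized internally).
#' @export
length_explicit <- function(lengths, probs) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) stop("explicit length model with empty support")
  if (length(lengths) != length(probs) || any(probs < 0) || sum(probs) <= 0)
    stop("probs must be non-negative, one per length, with positive total")
  if (any(lengths < 1L)) stop("lengths must be >= 1")
  structure(list(kind = "explicit", lengths = lengths,
                 probs = probs / sum(probs)),
            class = "length_model")
}

#' Sample read lengths
#'
#' @param model a length model ([length_fixed()], [length_normal()],
#'   [length_explicit()]).
#' @param n number of draws.
#' @return Integer vector of lengths (always >= 1).
#' @export
sample_length <- function(model, n = 1L) {
  switch(model$kind,
    fixed = rep(model$length, n),
    normal = {
      x <- round(rnorm(n, model$mean, model$sd))
      as.integer(pmin(pmax(x, model$min), model$max))
    },
    explicit = model$lengths[sample.int(length(model$lengths), n,
                                        replace = TRUE, prob = model$probs)],
    stop("unknown length model kind: ", model$kind))
}

#' @rdname sample_length
#' @return `max_length()`: the largest length the model can produce.
#' @export
max_length <- function(model) {
  switch(model$kind,
    fixed = model$length,
    normal = as.integer(min(model$max,
                            max(model$min, ceiling(model$mean + 6 * model$sd)))),
    explicit = max(model$lengths[model$probs > 0]))
}

#' Expected and realized read allocation across genomes
#'
#' The expected read count for genome *i* is proportional to
#' `abundance_i * size_i`: abundance is a cell-fraction, so the number of
#' fragments a genome contributes scales with both how common the organism
#' is and how much DNA each cell carries.  `allocate_reads()` realizes the
#' counts with one multinomial draw whose class probabilities are the
#' normalized expectations, so the counts sum to `total_reads` exactly.
#'
#' @param comp a [community_composition()].
#' @param db a [genome_db()] containing every genome of `comp`.
#' @param total_reads total number of reads.
#' @return Named numeric (expected) / integer (allocated) vector of counts.
#' @examples
#' db <- genome_db(c(A = strrep("A", 1500), B = strrep("C", 1000)))
#' comp <- community_composition(c(A = 0.4, B = 0.6))
#' expected_allocation(comp, db, 2e6)  # 1e6 each
#' @export
expected_allocation <- function(comp, db, total_reads) {
  missing <- setdiff(names(comp), names(db))
  if (length(missing) > 0)
    stop("composition genome(s) absent from the database: ",
         paste(missing, collapse = ", "))
  e <- as.numeric(comp) * genome_sizes(db)[names(comp)]
  if (sum(e) <= 0) stop("zero total expected mass")
  stats::setNames(total_reads * e / sum(e), names(comp))
}

#' @rdname expected_allocation
#' @export
allocate_reads <- function(comp, db, total_reads) {
  total_reads <- as.integer(total_reads)
  if (total_reads < 1L) stop("total_reads must be >= 1")
  e <- expected_allocation(comp, db, total_reads)
  if (length(e) == 1L)
    return(stats::setNames(total_reads, names(e)))
  stats::setNames(as.integer(rmultinom(1, total_reads, e / sum(e))), names(e))
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a fragment from a genome
#'
#' Substring `[start, start + length)` in 0-based half-open coordinates,
#' reverse-complemented when `strand == "-"`.
#'
#' @param db a [genome_db()].
#' @param genome_id genome to extract from.
#' @param start 0-based start.
#' @param length fragment length.
#' @param strand `"+"` or `"-"`.
#' @return The fragment as a character string.
#' @export
extract_fragment <- function(db, genome_id, start, length, strand = "+") {
  if (!genome_id %in% names(db)) stop("unknown genome: ", genome_id)
  gl <- nchar(db[[genome_id]])
  if (start < 0L || start + length > gl)
    stop("fragment [", start, ", ", start + length,
         ") out of bounds for genome ", genome_id, " (", gl, " bp)")
  frag <- substr(db[[genome_id]], start + 1L, start + length)
  if (strand == "-") reverse_complement(frag) else frag
}

# Precompute the sampling tables the C++ injector consumes.
.model_tables <- function(model) {
  probs <- model$qdist$probs
  sup <- which(colSums(probs) > 0)       # restrict to the observed support
  scores <- as.integer(colnames(probs))[sup]
  cdf <- t(apply(probs[, sup, drop = FALSE], 1L, cumsum))
  if (!is.matrix(cdf)) cdf <- matrix(cdf, nrow = nrow(probs))
  cond <- model$submat
  rs <- rowSums(cond)
  for (b in seq_len(4L)) {
    if (rs[b] > 0) cond[b, ] <- cond[b, ] / rs[b]
    else {                               # degenerate row: uniform over others
      cond[b, ] <- 1 / 3
      cond[b, b] <- 0
    }
  }
  list(qual_cdf = cdf, qual_scores = scores,
       err_prob = quality_to_error_prob(scores),
       type_cum = cumsum(model$proportions[c("ins", "del", "sub")]),
       sub_cum = t(apply(cond, 1L, cumsum)))
}

#' Inject sequencing errors into a template
#'
#' For each output cycle a PHRED score is drawn from the model's per-cycle
#' distribution; with probability `10^(-q/10)` an error is injected, its type
#' drawn from the (ins, del, sub) proportions.  Substitutions go through the
#' row-conditional substitution matrix (`N` templates emit a uniform random
#' base); insertions emit a uniform random base without consuming template;
#' deletions skip one template base and re-attempt the cycle.  The emitted
#' read has exactly `length` bases (`nchar(template)` by default), with the
#' drawn score reported as the quality of each emitted base — the quality
#' distribution is thus the single source of the error rate.
#'
#' @param template template string over `{A,C,G,T,N}`; pass a template
#'   longer than `length` to leave head-room for deletions.
#' @param model an [error_model()].
#' @param length number of bases to emit (default: the template length).
#' @return List with `sequence`, `qualities` (integer vector), `counts`
#'   (named: ins, del, sub), `consumed` (template bases used), `cigar` and
#'   `md` (the true alignment of read against template), and `exhausted`
#'   (`TRUE` if the template ran out before `length` bases were emitted).
#' @export
inject_errors <- function(template, model, length = nchar(template)) {
  tb <- .model_tables(model)
  r <- inject_errors_batch_cpp(template, as.integer(length), tb$qual_cdf,
                               tb$qual_scores, tb$err_prob, tb$type_cum,
                               tb$sub_cum)
  list(sequence = r$seq[[1]], qualities = r$qual[[1]],
       counts = c(ins = r$n_ins[[1]], del = r$n_del[[1]],
                  sub = r$n_sub[[1]]),
       consumed = r$consumed[[1]], cigar = r$cigar[[1]], md = r$md[[1]],
       exhausted = r$exhausted[[1]])
}

#' Simulation configuration
#'
#' @param total_reads total reads to emit (pairs count as two reads, so the
#'   total must be even in paired mode).
#' @param length_model a length model ([length_fixed()] etc.).
#' @param paired simulate read pairs?
#' @param insert_mean,insert_sd fragment-length normal model for paired mode;
#'   `insert_mean` must be at least twice the maximum read length.
#' @param bias optional named list of [coverage_profile()]s (one per genome);
#'   absent genomes fall back to uniform position sampling.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(total_reads, length_model, paired = FALSE,
                       insert_mean = NULL, insert_sd = NULL, bias = NULL,
                       seed = 1L) {
  total_reads <- as.integer(total_reads)
  if (total_reads < 1L) stop("total_reads must be >= 1")
  stopifnot(inherits(length_model, "length_model"))
  if (paired) {
    if (total_reads %% 2L != 0L)
      stop("paired mode needs an even total_reads")
    if (is.null(insert_mean) || is.null(insert_sd))
      stop("paired mode needs insert_mean and insert_sd")
    if (insert_mean < 2 * max_length(length_model))
      stop("insert_mean must be >= 2 * maximum read length")
  }
  if (!is.null(bias)) {
    ok <- vapply(bias, inherits, logical(1), "coverage_profile")
    if (is.null(names(bias)) || !all(ok))
      stop("bias must be a named list of coverage_profile objects")
  }
  structure(list(total_reads = total_reads, length_model = length_model,
                 paired = paired, insert_mean = insert_mean,
                 insert_sd = insert_sd, bias = bias,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate metagenome sequencing reads
#'
#' Reads are allocated to genomes by a multinomial on abundance x genome
#' size, positioned uniformly or by the coverage-bias profile, oriented with
#' probability 0.5 per strand, and (unless `model` is `NULL`) corrupted with
#' quality-driven substitution/indel errors.  Read identifiers encode the
#' true origin — `SIM|genome|start|end|strand|serial[/1|/2]` — so alignments
#' can be reconstructed without a mapper ([oracle_alignments()]).  Given the
#' same inputs and seed the output is deterministic.
#'
#' Under indels the emitted read keeps its drawn length: the template window
#' is over-fetched by `max(10, ceil(0.2 * length))` bases (toward the 3' end
#' in read orientation) to absorb deletions, and the rare read that exhausts
#' even that window is regenerated at a fresh position.  `start`/`end` record
#' the template span actually consumed.
#'
#' @param comp a [community_composition()].
#' @param db a [genome_db()]; every genome must be at least as long as the
#'   longest possible read (fragment, in paired mode).
#' @param model an [error_model()], or `NULL` for error-free reads (all
#'   qualities 40).
#' @param config a [sim_config()].
#' @return Object of class `simulated_reads` (also a `read_set`): parallel
#'   fields `id`, `seq`, `qual`, `genome_id`, `start`, `end`, `strand`,
#'   `n_ins`, `n_del`, `n_sub`, `cigar`, `md` (read-vs-template alignment),
#'   `mate` (index of the mate, `NA` single-end).  Write with
#'   [write_fastq()].
#' @export
simulate_reads <- function(comp, db, model, config) {
  stopifnot(inherits(comp, "community_composition"),
            inherits(db, "genome_db"), inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- genome_sizes(db)
  maxlen <- if (config$paired) {
    ceiling(config$insert_mean + 6 * config$insert_sd)
  } else max_length(config$length_model)
  short <- names(comp)[sizes[names(comp)] < maxlen]
  if (length(short) > 0)
    stop("genome(s) shorter than the maximum read/fragment length (",
         maxlen, " bp): ", paste(short, collapse = ", "))
  tables <- if (!is.null(model)) .model_tables(model) else NULL

  n_units <- if (config$paired) config$total_reads %/% 2L else
    config$total_reads
  alloc <- allocate_reads(comp, db, n_units)
  pieces <- vector("list", sum(alloc > 0))
  k <- 0L
  serial0 <- 0L
  for (g in names(alloc)) {
    if (alloc[[g]] == 0L) next
    k <- k + 1L
    if (config$paired) {
      p <- .sim_genome_paired(g, alloc[[g]], db, tables, config, serial0)
      p$mate <- p$mate + 2L * serial0   # block offset in the final ordering
      pieces[[k]] <- p
    } else {
      pieces[[k]] <- .sim_genome_single(g, alloc[[g]], db, tables, config,
                                        serial0)
    }
    serial0 <- serial0 + alloc[[g]]
  }
  out <- .rbind_reads(pieces)
  class(out) <- c("simulated_reads", "read_set")
  out
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat("simulated_reads:", length(x$id), "read(s) from",
      length(unique(x$genome_id)), "genome(s);",
      sum(x$n_ins + x$n_del + x$n_sub), "injected error(s)\n")
  invisible(x)
}

.rbind_reads <- function(pieces) {
  fields <- names(pieces[[1]])
  out <- lapply(fields, function(f) {
    v <- lapply(pieces, `[[`, f)
    if (f == "qual") do.call(c, v) else unlist(v, use.names = FALSE)
  })
  stats::setNames(out, fields)
}

# Sample start positions for n reads of lengths `lens` on genome g.
.sample_starts <- function(g, n, lens, glen, config) {
  prof <- if (!is.null(config$bias)) config$bias[[g]] else NULL
  if (is.null(prof)) {
    as.integer(floor(runif(n, 0, glen - lens + 1)))
  } else {
    if (prof$genome_length != glen)
      stop("coverage profile for ", g, " was estimated on a genome of ",
           prof$genome_length, " bp, not ", glen)
    iv <- sample.int(length(prof$weights), n, replace = TRUE,
                     prob = prof$weights)
    st <- (iv - 1L) * prof$interval_size +
      as.integer(floor(runif(n, 0, prof$interval_size)))
    pmin(st, glen - as.integer(lens))
  }
}

# Fetch oriented templates with 3'-ward over-fetch head-room for deletions.
# Nominal window is [start, start+len); "+" extends right, "-" extends left
# and is reverse-complemented.  Returns templates plus the genome coordinate
# of the template's far end in read orientation.
.fetch_templates <- function(genome, starts, lens, strands, margin, glen) {
  plus <- strands == "+"
  tmpl <- character(length(starts))
  lo <- integer(length(starts))
  hi <- integer(length(starts))
  lo[plus] <- starts[plus]
  hi[plus] <- pmin(starts[plus] + lens[plus] + margin[plus], glen)
  lo[!plus] <- pmax(starts[!plus] - margin[!plus], 0L)
  hi[!plus] <- starts[!plus] + lens[!plus]
  tmpl <- substring(genome, lo + 1L, hi)
  tmpl[!plus] <- reverse_complement(tmpl[!plus])
  list(tmpl = tmpl, lo = lo, hi = hi)
}

.sim_genome_single <- function(g, n, db, tables, config, serial0) {
  glen <- nchar(db[[g]])
  lens <- as.integer(sample_length(config$length_model, n))
  if (any(lens > glen))
    stop("genome ", g, " (", glen, " bp) shorter than a drawn read length")
  starts <- .sample_starts(g, n, lens, glen, config)
  strands <- ifelse(runif(n) < 0.5, "+", "-")
  r <- .generate_batch(db[[g]], glen, g, starts, lens, strands, tables,
                       config)
  r$id <- sprintf("SIM|%s|%d|%d|%s|%d", g, r$start, r$end, r$strand,
                  serial0 + seq_len(n))
  r$mate <- rep(NA_integer_, n)
  r[c("id", "seq", "qual", "genome_id", "start", "end", "strand",
      "n_ins", "n_del", "n_sub", "cigar", "md", "mate")]
}

.sim_genome_paired <- function(g, n_pairs, db, tables, config, serial0) {
  glen <- nchar(db[[g]])
  l1 <- as.integer(sample_length(config$length_model, n_pairs))
  l2 <- as.integer(sample_length(config$length_model, n_pairs))
  flen <- as.integer(round(rnorm(n_pairs, config$insert_mean,
                                 config$insert_sd)))
  flen <- pmin(pmax(flen, pmax(l1, l2)), glen)
  fs <- .sample_starts(g, n_pairs, flen, glen, config)
  fstrand <- ifelse(runif(n_pairs) < 0.5, "+", "-")
  # mate 1 sits at the 5' end of the fragment on its strand, mate 2 at the
  # other end, read inward (reverse-complemented relative to mate 1)
  s1 <- ifelse(fstrand == "+", fs, fs + flen - l1)
  s2 <- ifelse(fstrand == "+", fs + flen - l2, fs)
  str1 <- fstrand
  str2 <- ifelse(fstrand == "+", "-", "+")
  r1 <- .generate_batch(db[[g]], glen, g, as.integer(s1), l1, str1, tables,
                        config)
  r2 <- .generate_batch(db[[g]], glen, g, as.integer(s2), l2, str2, tables,
                        config)
  serial <- serial0 + seq_len(n_pairs)
  r1$id <- sprintf("SIM|%s|%d|%d|%s|%d/1", g, r1$start, r1$end, r1$strand,
                   serial)
  r2$id <- sprintf("SIM|%s|%d|%d|%s|%d/2", g, r2$start, r2$end, r2$strand,
                   serial)
  idx <- rep(seq_len(n_pairs), each = 2L)
  swap <- rep(c(2L, 1L), n_pairs) + 2L * (idx - 1L)
  fields <- c("id", "seq", "qual", "genome_id", "start", "end", "strand",
              "n_ins", "n_del", "n_sub", "cigar", "md")
  out <- lapply(fields, function(f) {
    v1 <- r1[[f]]; v2 <- r2[[f]]
    if (f == "qual") {
      v <- vector("list", 2L * n_pairs)
      v[seq(1L, 2L * n_pairs, 2L)] <- v1
      v[seq(2L, 2L * n_pairs, 2L)] <- v2
      v
    } else {
      v <- rep(v1, each = 2L)
      v[seq(2L, 2L * n_pairs, 2L)] <- v2
      v
    }
  })
  out <- stats::setNames(out, fields)
  out$mate <- swap
  out
}

# Core per-genome generation: fetch templates, inject errors (or copy
# faithfully), regenerate reads whose template was exhausted by deletions.
.generate_batch <- function(genome, glen, g, starts, lens, strands, tables,
                            config) {
  n <- length(starts)
  if (is.null(tables)) {
    tmpl <- .fetch_templates(genome, starts, lens, strands, rep(0L, n), glen)
    return(list(seq = tmpl$tmpl,
                qual = lapply(lens, function(l) rep(40L, l)),
                genome_id = rep(g, n), start = starts, end = starts + lens,
                strand = strands, n_ins = integer(n), n_del = integer(n),
                n_sub = integer(n), cigar = paste0(lens, "M"),
                md = as.character(lens)))
  }
  margin <- pmax(10L, as.integer(ceiling(0.2 * lens)))
  seq_out <- character(n); qual_out <- vector("list", n)
  st_out <- integer(n); en_out <- integer(n)
  ins <- integer(n); del <- integer(n); sub <- integer(n)
  cig <- character(n); md <- character(n)
  todo <- seq_len(n)
  for (round in 1:25) {
    f <- .fetch_templates(genome, starts[todo], lens[todo], strands[todo],
                          margin[todo], glen)
    r <- inject_errors_batch_cpp(f$tmpl, lens[todo], tables$qual_cdf,
                                 tables$qual_scores, tables$err_prob,
                                 tables$type_cum, tables$sub_cum)
    ok <- !r$exhausted
    done <- todo[ok]
    seq_out[done] <- r$seq[ok]
    qual_out[done] <- r$qual[ok]
    ins[done] <- r$n_ins[ok]; del[done] <- r$n_del[ok]
    sub[done] <- r$n_sub[ok]
    cig[done] <- r$cigar[ok]; md[done] <- r$md[ok]
    # consumed template span back to genome coordinates
    plus <- strands[done] == "+"
    st_out[done] <- ifelse(plus, f$lo[ok], f$hi[ok] - r$consumed[ok])
    en_out[done] <- ifelse(plus, f$lo[ok] + r$consumed[ok], f$hi[ok])
    todo <- todo[!ok]
    if (length(todo) == 0L) break
    # template exhausted by deletions: regenerate at a fresh position
    starts[todo] <- .sample_starts(g, length(todo), lens[todo], glen, config)
    strands[todo] <- ifelse(runif(length(todo)) < 0.5, "+", "-")
  }
  if (length(todo) > 0L)
    stop("could not generate ", length(todo), " read(s) for genome ", g,
         " without exhausting the template; deletion rate too extreme")
  list(seq = seq_out, qual = qual_out, genome_id = rep(g, n), start = st_out,
       end = en_out, strand = strands, n_ins = ins, n_del = del, n_sub = sub,
       cigar = cig, md = md)
}
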