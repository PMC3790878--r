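---
title: "shotsim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shotsim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical choices made where a
design question was genuinely open, and what the test suite does and does
not demonstrate.

## Overview

`shotsim` simulates shotgun metagenome sequencing in three stages, any of
which can be skipped when the corresponding information is already in
hand:

1. **Community composition** is either supplied as a table
   (genome → relative abundance) or estimated from alignments of an
   existing metagenome against the reference genomes.
2. **Platform models** — the per-cycle quality-score distributions, the
   insertion/deletion/substitution proportions, the substitution matrix,
   and per-genome coverage-bias profiles — are either taken from defaults
   or estimated from existing FASTQ + SAM data.
3. **Simulation** allocates reads to genomes, samples positions, lengths
   and strands, injects errors, and writes FASTQ.

## Composition estimation

A read aligned to exactly one genome adds 1 to that genome's count
(hitting one genome at several positions still counts as unique). After
all unique reads are counted, a read aligned to $n$ genomes distributes
total weight 1 with

$$w_i = \frac{m_i / s_i}{\sum_{j=1}^{n} m_j / s_j},$$

where $m_i$ is genome $i$'s unique count plus a pseudo-count (0.001 by
default) and $s_i$ its length in bases. The ratio $m_i/s_i$ is a
reads-per-base prior: a genome does not soak up shared reads merely by
being long. Genomes whose weighted count strictly exceeds a threshold
(10 by default) form the candidate list; their counts renormalize to
abundances.

Two choices here were genuinely open:

* **Two-pass weighting.** "Reads assigned so far" could mean a running
  total updated as multi-mapped reads are processed, which would make the
  result depend on read order. We freeze $m_i$ at the unique-read counts
  (plus pseudo-count), so the estimate is deterministic and permutation
  invariant; the tests assert this.
* **Pseudo-count placement.** The pseudo-count enters $m_i$, not the
  ratio, so two genomes with no unique support share a multi-read in
  inverse proportion to their sizes (equal sizes → 0.5/0.5), and the 0/0
  weight can never arise.

The per-read weights sum to 1, so before filtering, total count minus the
pseudo-count mass equals the number of assigned reads exactly — a
conservation law the tests check.

One semantic wrinkle is worth stating: estimation returns the *read
fraction* per genome, while simulation interprets abundance as a *cell
fraction* and multiplies by genome size to get expected reads. The two
coincide when genome sizes are equal (as in all bundled fixtures); with
unequal sizes, converting a read fraction to a cell fraction requires
dividing by genome size, which is left to the caller because the right
normalization depends on what the numbers will be used for.

## Error models

**Quality scores.** The PHRED score of an error probability $p$ is
$-10\log_{10} p$; FASTQ encodes score $q$ as the ASCII character
`q + offset`. The package follows the convention that offset 64 pairs
with Illumina models and offset 33 with 454 models, overridable at every
interface. Scores are capped at 62, the top of the printable offset-64
range.

**Per-cycle distributions.** Real per-cycle score distributions are
skewed, multi-modal and cycle dependent, so the model stores the full
empirical histogram at every cycle (a `quality_distribution`, rows
summing to 1 within 1e-9). Estimation is plain counting: the fraction of
reads covering cycle $c$ with score $q$. With ragged read lengths, deep
cycles are estimated from whatever reads reach them; a cycle with no
coverage borrows the nearest earlier estimated cycle, and simulation
beyond the estimation depth reuses the last cycle.

**Error-type proportions and substitution matrix.** Insertions and
deletions are counted from CIGAR `I`/`D` ops; substitutions by walking
the MD string against the read sequence, which yields the (reference
base → read base) pair for every mismatch. Soft-clipped bases are
excluded everywhere: they are not aligned evidence. Records without an
MD tag contribute indel counts only. When nothing was observed, platform
defaults apply: (ins, del, sub) = (0.01, 0.005, 0.985) for Illumina and
(0.2, 0.15, 0.65) for 454, and the published 454 substitution matrix,
whose 12 off-diagonal entries are treated as a **joint** distribution
over substitution pairs (they sum to 1 across the table, not per row);
during simulation the row of the actual template base is renormalized to
a conditional. No published Illumina matrix is bundled; the Illumina
default is a synthetic uniform matrix (1/12 per pair), clearly labelled
as such in its documentation, and is replaced by the estimated matrix
whenever substitution evidence exists.

**Synthetic default quality model.** `default_error_model()` provides a
complete model for simulations with no data to estimate from: platform
default proportions/matrix plus a synthetic per-cycle score distribution
whose mean decays linearly along the read (36 → 22 for Illumina, 32 → 24
for 454) with a ±3 triangular spread. This is a caricature of 3′-ward
quality decay, not an estimate of any dataset, and is the fixed model
under which the recovery tests run.

## Error injection

For each output cycle $c$: draw a score $q$ from cycle $c$'s
distribution; with probability $p = 10^{-q/10}$ inject an error; draw the
type from (ins, del, sub). A substitution replaces the current template
base through the conditional substitution matrix (a template `N` emits a
uniform random base; `N` is never a substitution *target*, keeping the
4-letter matrix well defined). An insertion emits a uniform random base
without consuming template. A deletion skips one template base and
re-attempts the same cycle with a fresh score draw. The emitted score is
reported as the base's quality, so the quality string and the error
process have a single common source — by construction, the simulated
error rate per read equals the model-implied value
$\sum_c E_q\!\left[\frac{p(q)}{1 - p(q)\,p_{del}}\right]$
(the denominator accounts for deletion re-attempts), which
`expected_errors_per_read()` computes in closed form and the tests check
at 150,000 reads.

Design choices:

* **Coupling.** Whether per-base errors should be driven by the drawn
  quality or by an independent global rate was open; we chose the
  coupling above so that the per-cycle quality histograms are the single
  source of the error rate and the emitted quality strings remain honest
  about the bases they annotate.
* **Constant read length under indels.** FASTQ consumers expect
  `length(sequence) == length(qualities)` and most pipelines assume the
  drawn read length. The template window is over-fetched by
  `max(10, 0.2 × length)` bases toward the 3′ end (in read orientation)
  to absorb deletions; a read that exhausts even that window — possible
  only near a genome end or under extreme deletion rates — is
  regenerated at a fresh position.
* **Strand.** Each read (fragment, in paired mode) is
  reverse-complemented with probability 0.5; sequencing is
  strand-symmetric.
* **Insertions** have no composition model of their own and emit uniform
  bases.

The per-read injection loop is implemented in C++ (Rcpp) with R's RNG, so
the exact procedure is affordable at the test sizes (10⁵–1.5×10⁵ reads)
and a seed reproduces output byte-for-byte. The documented draw order is:
allocation, then per read position → strand, then per cycle
score → error indicator → type → substitution/insertion base.

## Coverage bias

Genomes are divided into fixed-width intervals (100 bp by default); each
mapped read adds 1 to the interval containing its 0-based leftmost start
(leftmost, not 5′, following the SAM convention for reverse-strand
records), on top of a 0.1 pseudo-count floor, so every interval stays
sampleable. Sampling inverts this: interval ∝ weight, position uniform
within the interval, start clamped so the read fits. Clamping (rather
than wrapping) treats genomes as linear and slightly over-weights the
last valid window; the effect is one window per genome and is accepted
as documented behaviour. A read is binned by its start only — not spread
over the intervals it overlaps — which keeps estimation and sampling
exact inverses of each other. Profiles are keyed to the genome they were
estimated from; applying one to a genome of a different length is an
error, never a rescale.

## Allocation, lengths, pairs

Expected reads per genome are proportional to abundance × size, realized
with a single multinomial draw so counts sum exactly to the requested
total (a single-genome composition is deterministic). Read lengths come
from one of three models — fixed; rounded normal clamped to `[min, max]`;
or an explicit empirical distribution, which 454 length histograms
require. In paired mode the fragment length is drawn from
Normal(insert mean, insert sd) (rounded, clamped to at least the longer
mate and at most the genome), the fragment is placed and oriented like a
single read, and the two mates read inward from its ends; mate 2 is
reverse-complemented relative to mate 1. Whether real insert sizes are
normal was left open by the platform literature we model; the normal is
a documented choice.

## Evaluation and oracle alignments

`bc_distance()` normalizes both vectors to proportions before applying
$\sum_k |x_k - y_k| / \sum_k (x_k + y_k)$ — every comparison the package
makes (compositions, error-proportion triples, per-interval mean counts)
is proportional, and raw-count comparisons are an explicit opt-in
(`normalize = FALSE`). On normalized input the distance equals half the
L1 distance, which the tests verify algebraically and numerically.
`coverage_compare()` reports this BC plus the Pearson correlation on raw
weights (normalization cancels under Pearson), optionally truncated to
the first $n$ intervals.

Simulated read ids carry full provenance, and the simulator records the
true read-vs-template CIGAR/MD of every injected error, so
`oracle_alignments()` can emit the *true* alignment of every read without
a mapper. Reads with errors get their injected CIGAR/MD/NM — in read
orientation against the oriented template, with the strand folded into
the recorded coordinates — and error-free reads get a perfect-match
all-M record. A perfect-match record for every read would carry no error
signal and could not support closed-loop error-model recovery, which is
why the true alignment is kept; the records are exact for error,
coverage and composition re-estimation, though they are not
reference-strand SAM for a genome browser.

## The fixture generator

`make_fixture()` builds i.i.d. random genomes at a requested GC content,
plus a composition and optional sinusoidal coverage profiles
(weights $1 + 0.8\sin(2\pi k/20)$ per interval). Three presets mirror the
standard benchmark complexities: **LC** (2 genomes, 0.9/0.1, one
dominant), **MC** (9 genomes in 5 abundance levels —
2×0.28, 2×0.12, 2×0.06, 2×0.03, 1×0.02 — two dominant) and **HC**
(11 genomes at 1/11). The published MC design fixes only "nine species,
five levels, two dominant"; the level values above are this package's
choice of a realistic geometric-ish ladder under those constraints, made
once. Default genome length in the test suites is 100 kbp — long enough
that 100-bp reads from i.i.d. genomes are effectively unique, small
enough that the full suite runs in under two minutes.

What the fixtures emulate: community structure, coverage bias, platform
error mixes, quality decay. What they do not: real genomic repeat
structure, shared homology between community members, GC-coupled
coverage bias, homopolymer-driven 454 indels, chimeric/adapter artefacts.
Consequently a 100% unique self-mapping rate on HC fixtures is the
*expected* ceiling for repeat-free genomes, slightly above the ≈99.3%
seen with real genomes, and passing recovery tests demonstrate
correctness of the estimators, not that simulations are indistinguishable
from any particular instrument run.

## Problem sizes and tolerances used by the tests

* Composition recovery: 50,000 reads over 9 (MC) or 5 (custom) genomes;
  BC to truth < 0.05 (observed ≈ 0.003–0.007).
* Error-model recovery: 100,000 reads × 100 cycles; proportion BC < 0.01,
  per-cycle total variation < 0.02 (observed ≈ 0.0005 / 0.006).
* Coverage recovery: sinusoidal profile, 1,000 intervals at mean depth
  100; Pearson r > 0.9 (observed ≈ 0.98).
* Self-mapping: 150,000 error-free 100-bp reads from HC; ≥ 99.9% unique.
* Errors per read: observed mean within 3 standard errors of the
  closed-form expectation.

Numerical tolerances elsewhere: composition and quality-distribution
normalization to 1 within 1e-9; the substitution matrix total within
1e-4 (the published 454 table rounds to 5 decimals); model files are
written with 17 significant digits and round-trip bit-exactly.

## Known limitations

* No homopolymer-length-dependent 454 indel model, no SNP simulation, no
  PCR/amplicon simulation, no GC-parametric coverage model — coverage
  bias is deliberately an explicit empirical distribution.
* The composition estimator is a single weighted pass, not an EM
  iteration; heavily shared references (e.g. strain mixtures) will
  blur toward their unique-read support.
* Alignments are consumed as given; no re-alignment adjustment is
  applied to long-read mappings before error counting.
* Circular genomes are treated as linear (no reads across the origin).
* Multi-replicon organisms are separate sequences; nothing concatenates
  records, so per-organism aggregation is the caller's responsibility.
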