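Package: shotsim
Title: Metagenome Shotgun Sequencing Simulation with Empirical Error and
    Coverage-Bias Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates single-end and pair-end shotgun metagenome sequencing
    reads (Illumina- and 454-style) from a set of reference genomes and a
    community composition table.  Error models use the explicit empirical
    distribution of PHRED quality scores at every sequencing cycle, estimated
    from existing FASTQ/SAM data, together with insertion/deletion/substitution
    proportions and a substitution matrix parsed from NM/MD/CIGAR alignment
    fields.  Sequencing coverage bias is modelled as per-100-bp-interval
    sampling weights.  Community composition can be estimated from alignments
    of an existing metagenome by size-weighted sharing of multi-mapped reads.
    Simulation fidelity is evaluated with the Bray-Curtis dissimilarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
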