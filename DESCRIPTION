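Package: miredit
Title: Detection and Characterization of A-to-I miRNA Editing from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("miredit", "developers", email = "miredit@example.org", role = c("aut", "cre"))
Description: An offline-testable toolkit for adenosine-to-inosine (A-to-I)
    editing analysis of microRNAs in small RNA sequencing data, with a focus on
    extracellular-vesicle (EV) miRNA profiles. Reads are quality-gated,
    3'-tail trimmed and collapsed, then assigned by exact no-mismatch matching
    to unedited and single-site edited pre-miRNA references. Per-sample editing
    levels at catalogued sites are tested against a sequencing-error binomial
    null with Benjamini-Hochberg correction, filtered by read support and
    level, and aggregated into cross-sample high-confidence sites. The package
    also quantifies mature-miRNA expression (reads per million), predicts
    canonical 7-8mer 3'UTR seed targets for unedited versus edited miRNAs to
    measure target rewiring, and runs cohort-level editing-profile analysis
    (decision-tree imputation, rank-sum site selection, PCA, group
    comparisons). A seeded synthetic-data generator emits every input format
    the pipeline consumes, with truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    limma,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
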