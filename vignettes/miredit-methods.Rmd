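---
title: "Detecting A-to-I miRNA editing from small RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I miRNA editing from small RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miredit)
```

## The problem

Adenosine-to-inosine (A-to-I) editing by ADAR enzymes rewrites individual
adenosines in miRNA precursors. Sequencers read inosine as guanosine, so an
edited site appears as an A→G mismatch in reads covering it. Because a
mature miRNA is only ~22 nt and its target repertoire is largely determined
by the seed (nucleotides 2–8), a single edit can redirect a miRNA to a
substantially different target set. `miredit` detects and quantifies such
editing in small RNA-seq samples — including low-input material such as
extracellular-vesicle (EV) RNA from plasma, serum, or urine — restricted to
a user-supplied catalogue of known A-positions within mature miRNAs. De
novo site discovery is deliberately out of scope: with 16–25 nt reads and
no-mismatch alignment, an uncatalogued mismatch is indistinguishable from a
mapping artifact.

## The detection model

**Two-pass exact assignment.** Quality-filtered, 3′-trimmed, collapsed
reads are first matched as exact full-length substrings of the unedited
pre-miRNA hairpins. Only reads that fail this pass are matched against
single-substitution *edited references* — one per catalogued site, the
hairpin with G in place of A at that site. This replaces a no-mismatch
BLAST search: for full-containment, zero-mismatch queries of this length
the two contracts coincide, and substring matching is deterministic and
dependency-free. Three consequences of the design are worth noting:

* a read hitting an edited reference *outside* the substituted base is
  sequence-identical to the unedited hairpin and is routed to the unedited
  pass — counting it as edited would fabricate evidence;
* no read can be both unedited and edited (pass exclusivity);
* co-edited haplotypes (two sites altered in one molecule) are not
  enumerated; such reads match neither database and are dropped. This is a
  documented limitation, acceptable because catalogued sites rarely
  co-occur within one 22-nt window.

Reads matching k references receive fractional weight 1/k (the field has
no consensus treatment for multi-mapping small RNAs; fractional counting
keeps totals conserved and is symmetric across paralogs).

**Genomic exclusion.** An apparent edited read that also occurs verbatim
in the genome (either strand) is more parsimoniously explained as
transcription from another locus; such reads are demoted with reason
`genomic`. When no genome is supplied the stage is skipped with a logged
warning.

**Editing level and significance.** At each site,
level = edited count / coverage, where a read contributes to the edited
count only if its (collapsed mean) base quality at the substituted
position is ≥ 30. A masked edited read leaves numerator *and* denominator:
masking only the numerator would bias levels downward. Significance is a
one-sided upper-tail binomial test against the sequencing-error null,
P[X ≥ k | X ~ Bin(n, ε~AG~)], with Benjamini–Hochberg correction across
all candidate sites of the sample. A call passes when it has ≥ 2 edited
reads, level ≥ 5%, and BH q < 0.05. Sites passing with ≥ 2 edited reads in
≥ 10 samples are aggregated as high-confidence.

The error model ε~AG~ is either supplied or estimated as the Phred-implied
mean miscall probability of aligned bases divided by 3 (uniform miscall
direction). The estimate is computed from collapsed per-position mean
qualities — the only qualities that survive read collapsing — which makes
it slightly optimistic when per-read qualities vary widely (Jensen's
inequality); supplying a measured ε is preferred when one is available.
Fractional weighted counts are rounded half-up inside the binomial test
only; reported levels keep exact fractions.

## Tunable parameters

| parameter | default | unit / meaning |
|---|---|---|
| `max_n` | 5 | reads with more N bases are dropped |
| QC length window | 15–25 | nt, after adapter trimming |
| `min_mean_q` | 20 | mean Phred; ≤ 20 drops (boundary inclusive) |
| 3′ tail trim | 2 | max A/U bases removed from the 3′ end |
| final window | 16–25 | nt, retention after collapsing |
| `min_base_q` | 30 | Phred mask for G-supporting bases |
| `epsilon_ag` | estimated (fallback 0.001) | per-base A→G miscall probability |
| call gates | 2 reads, 5%, q < 0.05 | per-sample pass criteria |
| `min_rpm` | 10 | RPM expression retention |
| high-confidence | 10 samples, 2 reads | cross-sample aggregation |
| dataset gates | 1e6 clean reads, 60% bases, 1e5 mapped | per-dataset QC |
| `select_alpha` | 0.1 | cohort site-selection p threshold |

All defaults are the published values of the method this package
implements; every one is a named `pipeline_config()` parameter, overrides
are recorded in the run log, and the gates can be relaxed individually for
desk-scale testing. Two deliberate readings of ambiguous prose: the QC
window (15–25) and the final retention window (16–25) are both enforced,
in that order, as written; and "mean quality ≤ 20" is an inclusive drop at
exactly 20.

One ordering choice differs from the described sequence: 3′ A/U trimming
is applied *before* collapsing. Collapsing first would keep 3′-tailed
variants of the same molecule apart, defeating the purpose of the rule;
trimming first merges them. The keep/drop decisions of each gate are
unchanged by this order.

## What the simulator does and does not emulate

`simulate_references()` / `simulate_reads()` generate hairpins (60–90 nt,
20–23 nt arms on both duplex strands), site tables (positions biased
towards mature positions 2 and 5, where editing is most often observed in
vivo; the reference base is forced to A during construction, which is
equivalent to resampling hairpins until an A is available but cheaper and
deterministic), decoy genomes (hairpin loci plus unrelated sequence, with
optional planted edited-read decoys), random 3′UTR collections, and
per-sample FASTQ with truth tables.

Reads are simulated under exactly the statistical model the caller tests
against: per-read Bernoulli editing at the true level, then independent
per-base miscalls. In the default mode each base is miscalled at
10^(−Q/10) under its own drawn Phred score (clipped normal around
`phred_mean` = 35, sd 3). In the fixed-ε mode every base is miscalled at a
constant rate while quality strings are still drawn around `phred_mean`;
the two are decoupled on purpose, because encoding ε = 0.01 as its literal
Phred value (Q20) would produce reads that the mean-quality gate deletes
wholesale, leaving nothing for the calibration experiments this mode
exists for. A configurable fraction of reads receives a 1–2 nt
non-templated 3′ A/U tail to exercise the trimmer.

Not emulated: ligase bias, isomiR length heterogeneity, template-switching
artifacts, EV-isolation batch effects. A green synthetic test therefore
establishes correctness of the statistical machinery under its stated
assumptions — not robustness to every artifact of real libraries.

## Target rewiring

Inosine pairs like guanosine in a duplex, so the edited miRNA is modelled
as its A→G substituted sequence. Both forms are scanned against 3′UTRs for
the three canonical site types (8mer, 7mer-m8, 7mer-A1, with priority
8mer > 7mer-m8 > 7mer-A1 at a shared register). Full TargetScan-style
context scoring and conservation filtering are out of scope: the rewiring
statistic needs only site presence. Overlap between the unedited and
edited target sets is reported as Jaccard, |A∩B|/|A∪B| (0 when both sets
are empty), with "fraction of unedited targets retained" available as an
alternative — the literature quotes overlap percentages without printing a
formula, so the metric is an explicit, documented choice here. Targets are
counted at the transcript (UTR record) level. Editing positions are
annotated by functional domain: nt 1 the 5′ anchor, 2–8 seed, 9–12
central, 13–16 3′ supplementary, ≥ 17 3′ tail.

## Cohort analysis

The editing matrix (sites × samples) holds the level of every emitted
call, passing or not, with NA where a site had no coverage. Sites are
selected for PCA when a two-sided rank-sum test between the reference
(healthy) group and any other condition gives p < 0.1, unadjusted, on raw
levels; no missingness-based exclusion is applied. Missing cells are then
imputed per condition by a regression tree predicting each incomplete site
from the other sites (training on samples where the target is observed,
predictors mean-filled, predictions clipped to [0,1]); observed cells are
never altered and the procedure is deterministic. The tree is a small
in-package CART (greedy variance-reduction splits, grown to purity,
first-feature/lowest-threshold tie-breaks) because no tree package is
available in the supported dependency set; it matches the defaults of the
common scikit-learn regressor in the regimes used here.

PCA runs on centered, unscaled levels — levels already share a unit, so
scaling would up-weight noise at near-constant sites; a scaling flag
exists. Component signs follow a fixed convention (largest-magnitude
loading positive) so runs are reproducible. Group comparisons use the same
rank-sum test on raw (non-imputed) levels with the usual asterisk tiers
(* p < 0.05, ** p < 0.01), direction by median difference with mean
difference as tie fallback, and no multiplicity correction (the tiers
describe per-site panels, not a discovery screen).

The rank-sum test is implemented in-package with midranks and exact
enumeration of the permutation null when the group sizes allow
(≤ 2×10^5 combinations), because the stock implementation abandons the
exact null in the presence of ties — and bounded editing fractions tie
routinely. Larger groups use the normal approximation with tie and
continuity corrections.

## Numerical choices and degenerate inputs

* BH is the standard step-up with monotonicity enforcement; the universe
  is all candidate sites with coverage ≥ 1 in one sample.
* Zero-coverage sites emit no call; zero-mapped-read samples are a hard
  error in expression (RPM would divide by zero).
* A site missing in *all* samples of a condition is imputed with its
  global mean, with a warning; a site observed nowhere is an error.
* Constant matrices are rejected by PCA (zero variance).
* Hairpins outside 40–200 nt and arms outside 15–30 nt warn rather than
  error, so that deliberately small didactic examples remain usable;
  out-of-bounds intervals and non-A site bases are hard errors.
* Single-batch input to the batch hook is an identity pass-through with a
  warning; the hook delegates to a linear-model batch remover and makes no
  claim beyond that delegation.

## Known limitations

Catalogue-anchored detection cannot find novel sites. Exact matching
discards reads with any sequencing error in the matched window, which
lowers usable coverage at low qualities (unbiased for level estimates, but
a loss of power). Co-edited reads are unassigned. The error-rate estimator
inherits the collapsed-quality approximation described above. RPM is
computed from mature-attributed reads only, so it is a within-sample
relative measure over the supplied reference set, not an absolute
abundance.
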