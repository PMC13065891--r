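# miredit

Detection and characterization of A-to-I (adenosine-to-inosine) miRNA
editing from small RNA sequencing data.

ADAR enzymes deaminate adenosines in miRNA precursors; sequencers read the
resulting inosine as guanosine, so editing shows up as A→G mismatches in
reads. Because target recognition is dominated by the 7-nt seed
(nucleotides 2–8 of a ~22-nt mature miRNA), one edit can redirect a miRNA
to a largely different target set. `miredit` is aimed at researchers
profiling miRNA editing in bulk small RNA-seq — including low-input
extracellular-vesicle (EV) samples from plasma, serum, urine, or culture
media — against a catalogue of known editing sites.

## What it computes

Given pre-miRNA hairpins, mature-arm annotation, a table of known editing
sites, and FASTQ reads, the pipeline:

1. **QC + collapsing** — drops reads with >5 ambiguous bases, length
   outside 15–25 nt, or mean Phred ≤ 20; trims up to two 3′-terminal A/U
   bases (non-templated tailing); collapses identical reads; retains
   16–25-nt sequences. Datasets are gated at 1e6 clean reads, 60% bases
   retained, and 1e5 mapped reads.
2. **Two-pass exact assignment** — reads are matched as exact full-length
   substrings of the unedited hairpins, then (if unmatched) of per-site
   edited references (the hairpin with A→G at one catalogued site). An
   edited hit must cover the substituted base. Apparent edited reads that
   occur verbatim in the genome (either strand) are excluded.
3. **Editing calls** — per site: level = edited reads / coverage (G-reads
   quality-masked at Phred 30), one-sided binomial test against the
   sequencing-error rate ε, BH correction per sample. A call passes with
   ≥2 edited reads, ≥5% level, q < 0.05. Sites passing in ≥10 samples
   (≥2 reads each) are high-confidence.
4. **Expression** — RPM = miRNA mapped reads / total mapped reads × 1e6,
   retained at ≥10 RPM, with a batch-correction hook.
5. **Target rewiring** — canonical 8mer / 7mer-m8 / 7mer-A1 3′UTR sites
   for the unedited vs edited mature sequence; Jaccard overlap of the two
   target sets; functional-domain annotation of the edit position.
6. **Cohort analysis** — sites × samples editing matrix, rank-sum site
   selection (p < 0.1 vs the reference condition), per-condition
   decision-tree imputation, PCA, per-site group comparisons.

A seeded synthetic-data generator (`sim_config()`,
`simulate_references()`, `simulate_reads()`, `simulate_editing_matrix()`)
produces every input format with truth tables, so the whole pipeline is
testable offline.

## Worked example

```r
library(miredit)

cfg <- sim_config(n_hairpins = 5, n_sites = 3, coverage = 500,
                  epsilon = 0.001, editing_levels = c(0.05, 0.2, 0.4),
                  seed = 7)
sim <- simulate_references(cfg)
sr  <- simulate_reads(sim, 1, sample_id = "plasma_1")

pre <- preprocess_reads(sr$reads)
asn <- assign_reads(pre$collapsed, sim$refs, sim$edited)
asn <- exclude_genome_matchers(asn, sim$genome)
e   <- estimate_error_rate(pre$collapsed, asn)
calls <- call_sites(pileup_sites(asn, pre$collapsed, sim$sites),
                    e, "plasma_1")
print(calls, digits = 3)
#>   sample_id site_id coverage edited_count  level   p_value   q_value passes
#> 1  plasma_1  site01      489           28 0.0573  1.63e-66  1.63e-66   TRUE
#> 2  plasma_1  site02      493           98 0.1988 1.17e-284 1.75e-284   TRUE
#> 3  plasma_1  site03      490          179 0.3653  0.00e+00  0.00e+00   TRUE
```

The three sites were planted at true levels 0.05, 0.2 and 0.4; the
estimated levels (5.7%, 19.9%, 36.5%) sit within binomial noise of truth
at ~490× coverage, and all three clear the support, level, and q-value
gates. Expression and rewiring from the same objects:

```r
rpm <- compute_rpm(attribute_mature(asn, sim$refs), "plasma_1")
head(rpm[order(-rpm$rpm), ], 3)
#>   sample_id mature_id mapped_reads    rpm retained
#> 3  plasma_1   hp02-3p          494 100919     TRUE
#> 4  plasma_1   hp02-5p          493 100715     TRUE
#> 7  plasma_1   hp04-3p          491 100306     TRUE

s   <- sim$sites[2, ]
arm <- sim$refs$arms[sim$refs$arms$mature_id == s$mature_id, ]
rewire_targets(arm$mature_seq, s$mature_pos, sim$utrs)[c("domain", "overlap")]
#> $domain
#> [1] "seed"
#> $overlap
#> [1] 0
```

RPM sums to 1e6 across the ten arms (uniform coverage → ~100,000 each);
the seed-region edit at `site02` moves the miRNA to a disjoint predicted
target set (Jaccard overlap 0 on this synthetic UTR collection).

The same run as one call: `run_pipeline(pipeline_config(...))`, or from
the shell via the installed CLI:

```sh
inst/cli/miredit simulate --out sim --seed 3 --n-samples 2
inst/cli/miredit run-all --premirna sim/hairpins.fa --mature sim/mature.tsv \
    --sites sim/sites.tsv --fastq s1=sim/s1.fastq,s2=sim/s2.fastq \
    --genome sim/genome.fa --out run \
    --min-clean-reads 100 --min-frac-bases 0.5 --min-mapped-reads 100
```

Exit codes: 0 ok, 2 dataset excluded by QC, 1 error.

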