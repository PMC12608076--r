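---
title: "Calling allelic regulatory variants from barcoded MPRA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling allelic regulatory variants from barcoded MPRA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpracall)
```

# The assay and the analysis problem

A massively parallel reporter assay (MPRA) clones thousands of candidate
regulatory sequences into a reporter plasmid, tags every clone with a
degenerate 20-bp barcode in the reporter 3' UTR, transfects the library into
cells, and sequences barcodes from both the input plasmid pool and the
reporter mRNA. The ratio of a sequence's RNA barcode counts to its plasmid
counts measures its transcriptional activity. When the library carries
multiple alleles of the same variant on otherwise identical 170-bp genomic
fragments, the between-allele activity ratio measures the variant's allelic
(genotype-dependent) regulatory effect. Because the reporter uses a
moderate-strength promoter rather than a minimal one, activity can move in
both directions, so both enhancer-like and silencer-like effects are
observable.

`mpracall` implements the full analysis path: oligo design from variant
records, barcode-to-oligo association from paired-end reads, per-sample
barcode quantification, negative-binomial activity calling against plasmid
controls, allelic calling, resampling enrichment of variant sets in
ChIP-seq peak files, and direction-matched eQTL gene annotation. A
synthetic-data generator plants known effects so every stage can be
validated against ground truth; all statements below about error control
and power are backed by the package's test suite and
`scripts/acceptance.R`, which recompute them.

# Library design

Variant records are screened before synthesis: any allele longer than 10
bases, or containing a homopolymer run longer than 4, disqualifies the
variant (`filter_variants()`). The homopolymer rule is applied to allele
sequences by default; screening whole cores instead is left to callers
because the bound is a synthesis-fidelity constraint whose scope is
genuinely ambiguous — allele-level is the less destructive reading.

Each retained allele is embedded in a 170-bp core: 84 bases of upstream
flank, the allele starting at position 85, and enough downstream flank to
reach exactly 170 bp, so indel alleles absorb their length difference
downstream (`build_core()`). Flanks are identical across the alleles of one
variant; cores therefore differ only inside the allele span. Every core is
emitted in both orientations — the forward core and its reverse complement —
wrapped in fixed 15-bp cloning adapters (`ACTGGCCGCTTGACG`,
`CACTGCGGCTCCTGC`) to form the 200-bp synthesis sequence
(`emit_oligos()`). The two orientations are technical duplicates guarding
against strand-specific synthesis errors; downstream testing pools their
counts per (variant, allele) by default, with a flag to keep them separate.

# Read processing

**Association.** Paired-end reads of the cloned library link barcodes to
oligos. Reads are quality-trimmed from both ends (default thresholds Q25 /
Q25, minimum length 80). The first 20 bases of read 1 are the barcode; the
remainder, together with read 2, is matched against the designed oligo
sequences allowing up to 2 substitutions per mate and no indels
(`match_oligo()`) — designed references are known and short, so a full
aligner adds nothing but nondeterminism. Pairs fitting more than one oligo
equally well (for example when neither mate covers the allele base) are
discarded as ambiguous. Barcodes containing N are dropped. Per barcode, the
modal oligo is kept when it has at least 2 supporting reads and at least
90% purity; conflicted barcodes are discarded rather than rescued
(`build_barcode_map()`). The thresholds are arguments; the conservative
default loses a small amount of library rather than risk cross-oligo count
bleed.

**Quantification.** Single-end tag reads are the barcode followed by a
constant region of the reporter 3' UTR. After trimming (Q3 / Q3, minimum
70), a read is kept only if its constant window is within Levenshtein
distance 4 of the reference constant region and the two bases directly
adjacent to the barcode match exactly (`filter_tag_reads()`). Barcode
lookup is exact-match; 20-mers at library scale make 1-mismatch rescue
unnecessary and it is deliberately not implemented. Barcode counts are
summed to oligo level, preserving column totals exactly and retaining
per-oligo unique-barcode tallies for the downstream filter
(`aggregate_to_oligo()`).

# Activity calling

Only units with at least 30 unique barcodes across the union of plasmid
replicates are tested; a per-replicate variant of the filter is available.
The differential test follows the standard RNA-seq formulation:

* **Normalization** — median-of-ratios size factors over units with
  all-positive counts (`size_factors()`).
* **Dispersion** — per-unit method-of-moments estimates pooled across the
  two conditions, shrunk toward a mean–dispersion trend
  `a0 + a1 / mean` fitted across units, floored at 1e-8
  (`estimate_dispersion()`, `prior_df = 10`). With 10 samples the shrunk
  estimate weighs the per-unit estimate and the trend roughly equally.
* **Test** — a per-unit negative-binomial GLM with log link, a
  plasmid-vs-RNA indicator and log size-factor offsets, fitted by a
  vectorized IRLS over all units simultaneously, with a Wald test on the
  condition coefficient (`test_activity()`). The Wald statistic is referred
  to a t distribution with n − 2 degrees of freedom rather than the normal:
  with five replicates per condition the plug-in dispersion makes the
  normal reference anti-conservative in exactly the far tail that matters
  after multiple-testing correction. A `ref_dist = "normal"` option
  restores the asymptotic reference.

All-zero RNA rows cannot be fitted at an interior optimum; they are
refitted with a half-count, flagged, and reported with a `-Inf` fold-change
sentinel. A unit is an **enhancer allele** if its BH-adjusted p-value is
below 0.05 and its fold change exceeds 1.2, a **silencer allele** below
1/1.2; the BH family is all retained units within one cell line. A variant
is an enhancer (silencer) variant in a cell line if any of its alleles is.
A (variant, allele) called enhancer in one cell line and silencer in
another is flagged contradictory and excluded from allelic analysis;
opposite calls through *different* alleles within one line are kept, since
they are biologically coherent. The calling agrees closely with DESeq2 on
identical inputs (correlation of fold changes > 0.98 in the cross-check
test); exact dispersion-shrinkage internals (Cox–Reid adjustment, LFC
shrinkage, independent filtering) are intentionally not reproduced because
the decision rule uses raw fold changes against a hard threshold.

# Allelic calling

Only enhancer or silencer variants are tested. For each nonreference
allele against the reference, `call_allelic()` forms the per-replicate
log2 nonreference/reference count ratio (size-factor normalized, with a
0.5 pseudocount) in the RNA replicates *and* in the plasmid replicates,
and compares the two groups with a pooled-variance Student's t-test
(`allelic_test()`). The reported effect,
`log2_ratio = mean(RNA ratios) − mean(plasmid ratios)`, is the
plasmid-normalized allelic activity ratio.

This contrast is the one place the implementation departs from the more
obvious construction (computing each allele's plasmid-normalized activity
per RNA replicate and t-testing the two activity vectors). That
construction hides the plasmid normalization noise from the test: both
activity vectors are shifted by their allele's *estimated* plasmid mean,
a shared random offset that inflates the t statistic by roughly sqrt(2)
when plasmid and RNA counts are comparably deep. Measured on null
simulations, the activity-vector contrast yields P(p < 0.01) ≈ 0.04 and an
uncontrolled false discovery proportion among allelic calls, while the
ratio-vs-plasmid-ratio contrast is calibrated (P(p < 0.01) ≈ 0.01).
Both groups of ratios are independent observations, so the normalization
noise correctly enters the null distribution. `allele_activity()` is still
exported for diagnostics.

A pair is **allelic** if its BH-adjusted p-value (family: all pairs in the
cell line) is below 0.05 and |log2 ratio| ≥ log2(1.2) — the "20%" rule,
inclusive at the boundary. The label (allelic enhancer / allelic silencer)
follows the variant's activity class. Multi-allelic variants contribute one
pair per nonreference allele and are allelic if any pair is; identical
degenerate vectors return p = 1, and zero-variance unequal vectors p = 0.
Cross-cell-line summaries are set unions, never sums.

# Peak enrichment

`reli_test()` compares the observed number of input variants inside a peak
dataset against a null of 2,000 equally sized draws from the negative set —
all variants in the library — sampled uniformly without replacement (no
LD or feature matching, matching the plain-resampling design). It reports
the null mean and sd, a z-score (sd floored at 1e-9), and the add-one
empirical p-value `(1 + #{draws ≥ observed}) / (iterations + 1)`, which
can never return 0 and floors at 1/2001 at the default iteration count.
Coordinates follow BED convention: peaks are 0-based half-open, variant
positions 1-based, so position p overlaps [start, end) iff
start < p ≤ end. Overlap is computed through GenomicRanges interval
indexing. `run_battery()` crosses input sets with peak datasets and applies
Bonferroni across datasets within each input set (BH is a flag), mirroring
how resampling enrichment batteries are conventionally reported.

# Gene annotation

eQTL records (a local TSV snapshot; reproducible and offline) are filtered
to the configured tissue label and nominal p < 0.05, harmonized so the
effect refers to the nonreference allele (the beta sign flips when the
effect allele is the reference), and kept only when the harmonized effect
sign matches the sign of the allelic log2 ratio (`direction_match()`).
Records whose effect allele matches neither tested allele are dropped and
tallied rather than raised, because public tables mix strands and builds;
with multi-allelic variants an eQTL row can legitimately describe an
allele other than the tested pair's. Gene lists per allelic class are
tested for over-representation in GMT gene sets with one-sided Fisher's
exact tests against the gene universe of the eQTL table (the reachable
annotation space), BH across sets, flagging overlaps below 5 as below the
display threshold.

# The synthetic study generator

`sim_config()` encodes the emulated study structure: a mean of 2.7 alleles
per variant (2 + a truncated-Poisson excess with the rate solved to hit the
mean), a median of 239 unique barcodes per oligo (log-normal around the
median, log-sd 0.5 — the real barcode-count distribution is not published,
and a heavy-tailed log-normal is the standard model for plasmid library
composition), 5 plasmid and 5 RNA replicates per cell line, 3 cell lines,
and a shared NB dispersion (default 0.05). Planted fractions default to
8% enhancer and 15% silencer variants with 13% of regulatory variants
allelic, matching the emulated study's reported proportions. The default
library size is a desk-scale 500 variants across 50 loci — the full-scale
study (about 14,000 variants) differs only in runtime.

Counts are NB around log-normal per-barcode abundances scaled to the
sample depth; RNA means are multiplied by each oligo's planted activity
(fold change, times the allelic ratio on nonreference alleles) and
rescaled to depth, so relative effects are preserved exactly and column
totals are conserved. An optional per-cell-line activity jitter (off by
default, since the null study has no line effects) makes replicates
cluster by line for QC validation. Counts can be simulated at barcode or
directly at oligo level; the oligo level is used where barcode structure
is irrelevant and 10,000-oligo simulations must run in seconds.
Association reads are barcode + oligo prefix / oligo-suffix mate pairs,
tag reads are barcode + constant region + fixed filler, both with a
configurable uniform substitution error rate (capped at 0.2). Every
generator derives a stage seed from the master seed, so outputs are
byte-identical under a fixed seed and stages can be regenerated
independently.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: chromatin context and transfection biology,
barcode-level PCR jackpotting beyond the log-normal, replicate-specific
library composition drift, LD structure among variants, sequencing quality
degradation profiles, and real eQTL effect-size distributions. The error
model is uniform substitution only.

# Numerical choices and degenerate inputs

* IRLS: at most 50 iterations, convergence at 1e-8 coefficient change,
  means clamped to [1e-10, 1e12]; rows with a singular working information
  keep their previous iterate.
* Dispersion floor 1e-8; trend fitted only when at least 10 usable units
  exist, otherwise the median raw estimate (or the floor) is used.
* Pseudocount 0.5 in allelic ratios keeps zero-count replicates finite.
* `size_factors()` errors (suggesting a pseudocount) when no unit has
  all-positive counts rather than silently degrading.
* Ties in `build_barcode_map()` resolve by read support, then
  lexicographic oligo id — deterministic across runs.
* Empirical enrichment p-values use the add-one estimator; with heavily
  tied overlap counts they are mildly super-uniform, which the calibration
  test tolerates by construction (KS at alpha = 0.01).
* `bh_adjust()` validates p in [0, 1] and refuses NAs rather than
  propagating them into the step-up formula.

# Problem sizes in the test suite

The suite exercises the stated study conditions at sizes chosen to keep a
single-CPU run comfortable: oracle equivalence exhaustively over all DNA
pairs up to length 4 plus sampled longer pairs, and all 2x2 tables with
total ≤ 16 plus sampled tables to total 60; read-level round trips at 500
variants with 5 + 5 samples; null error control on 20 simulations of a
~10,000-oligo library at dispersion 0.05; recovery at planted fold change
2.0 and allelic ratio 1.5 with ≥ 100 barcodes per oligo; enrichment
calibration over 200 resampling runs at 2,000 iterations; and an
end-to-end run at 500 variants with three cell lines. The same quantities
are recomputed from scratch by `scripts/acceptance.R`.

# Known limitations

* The NB test's t reference is a calibration device, not an exact
  small-sample distribution; extremely deep counts with many replicates
  would make the normal reference preferable.
* Orientation pooling assumes the two orientations are exchangeable; a
  sequence with strong orientation-dependent activity would be averaged.
* The allelic test operates on per-replicate ratios, not per-barcode
  ratios; barcode-level mixed models are out of scope.
* Enrichment draws are matched on set size only; confounders correlated
  with peak density (GC, distance to genes) are not controlled.
* The homopolymer filter, applied to alleles, cannot reject a flank-borne
  run introduced by the surrounding genome.
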