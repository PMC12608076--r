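# mpracall

Allelic regulatory variant calling for barcoded massively parallel
reporter assays (MPRA).

Disease-associated variants overwhelmingly fall in noncoding DNA, where
they may act by changing regulatory element activity. An MPRA tests
thousands of candidate sequences at once: each 170-bp genomic fragment
(one allele of one variant, synthesized in both orientations inside fixed
cloning adapters) is tagged with degenerate 20-bp barcodes, cloned into a
reporter plasmid, and transfected; sequencing barcodes in the reporter
mRNA and in the input plasmid pool gives, per fragment, an activity
readout. With a moderate-strength promoter, both directions are visible:
**enhancer** alleles raise reporter transcription, **silencer** alleles
lower it, and **allelic regulatory** variants are regulatory variants
whose alleles differ from each other.

`mpracall` implements the complete analysis path as a tested R package
plus an analysis workflow:

1. **Design** — variant filters (allele length ≤ 10, homopolymer runs ≤ 4)
   and 170-bp core / 200-bp oligo construction (`filter_variants()`,
   `build_core()`, `emit_oligos()`).
2. **Association** — barcode→oligo maps from paired-end reads with
   quality trimming, substitution-budget matching, and a
   support/purity-filtered modal assignment (`associate_barcodes()`,
   `build_barcode_map()`).
3. **Quantification** — tag-read filtering by Levenshtein distance ≤ 4 on
   the constant region with exact junction bases, exact barcode counting,
   and oligo-level aggregation (`quantify_sample()`,
   `aggregate_to_oligo()`).
4. **Activity calling** — for units with ≥ 30 plasmid barcodes, a
   negative-binomial GLM of RNA vs plasmid counts with median-of-ratios
   size factors and trend-shrunk dispersions; enhancer/silencer alleles at
   BH FDR < 0.05 and fold change beyond 1.2× either way; variant rollup
   with cross-cell-line contradiction screening (`call_activity()`,
   `rollup_variants()`).
5. **Allelic calling** — Student's t-test of per-replicate log2
   nonreference/reference count ratios in RNA vs plasmid replicates,
   FDR < 0.05 with a ≥ 20% between-allele effect (`call_allelic()`).
6. **Enrichment** — resampling overlap tests of called variant sets
   against ChIP-seq peak BED files, with the whole library as negative
   set and 2,000 draws (`reli_test()`, `run_battery()`).
7. **Annotation** — direction-matched eQTL gene assignment and Fisher
   over-representation on GMT gene sets (`annotate_genes()`,
   `overrepresentation()`).

A synthetic-data module (`sim_config()`, `simulate_library()`,
`simulate_counts()`, `simulate_association_reads()`,
`simulate_tag_reads()`, `simulate_peaks_eqtls()`) generates studies with
planted effects — the replicate structure, allele multiplicity (mean 2.7
per variant) and barcode depth (median 239 per oligo) of the emulated
assay — so every stage is validated against ground truth.

## The statistics at the core

For unit *i* with counts *y\_ij* in sample *j* (size factor *s\_j*,
condition *x\_j* ∈ {plasmid, RNA}):

* activity: *y\_ij* ~ NB(*μ\_ij*, *α\_i*), log *μ\_ij* = β₀ᵢ + β₁ᵢ·*x\_j* +
  log *s\_j*; Wald test on β₁ᵢ (t reference, df = n − 2); enhancer iff
  BH-adjusted p < 0.05 and 2^β₁ > 1.2, silencer iff 2^β₁ < 1/1.2.
* allelic: *r\_j* = log₂((*y\_NR,j*/*s\_j* + ½)/(*y\_R,j*/*s\_j* + ½));
  pooled t-test of {*r\_j* : RNA} vs {*r\_j* : plasmid}; allelic iff
  BH-adjusted p < 0.05 and |mean difference| ≥ log₂ 1.2.
* enrichment: empirical p = (1 + #{null draws ≥ observed}) / (N + 1) over
  N = 2,000 equal-size draws from the library.

## Worked example

The numbered scripts under `analysis/` run a 500-variant synthetic study
end to end (`Rscript analysis/01_simulate.R` … `07_report.R`), writing
tables under `results/analysis/`. Output from a run:

```
== 01_simulate ==
Simulated study: 500 variants (50 loci), 2720 oligos, 180428 barcodes.
Planted: 42 enhancer, 79 silencer variants; 20 with allelic effects.
== 02_associate_quantify ==
Associated 541284 read pairs: 180428 barcodes mapped (median 58 per oligo).
Truth-map recovery exact: TRUE; count-table recovery exact: TRUE.
== 03_activity ==
Across cell lines (union): 44 enhancer, 79 silencer variants;
sensitivity vs planted truth: enhancers 1.00, silencers 1.00;
false-positive variants among neutrals: 2; contradictory calls: 0.
== 04_allelic ==
Union across cell lines: 22 allelic variants (20 planted; 0.95 of
planted recovered; 3 calls on non-allelic variants).
== 05_enrichment ==
  allelic_silencer  -> enriched   obs 12 vs null 1.6 (z 8.9, p 5.00e-04)
```

Reading these numbers: association and quantification reproduce the
simulator's truth exactly on error-free reads; the activity caller finds
every planted regulatory variant at this depth with two false positives
among 379 neutral variants (FDR-consistent); 19 of 20 planted allelic
variants are recovered; and the peak dataset constructed to cover allelic
variants is the top enrichment hit for the allelic sets, while uniform
background datasets stay null.

The same drivers work on real data by replacing stage 1's outputs: a
variant TSV and flank FASTA for the design stage, FASTQ for stages 2–3, a
sample sheet TSV, peak BED files, an eQTL TSV and GMT gene sets for
stages 5–6 (see `External Interfaces` in the function documentation).

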