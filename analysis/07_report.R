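# Stage 7: study report. Replicate QC (correlation clustering) and
# per-locus summaries of regulatory and allelic regulatory variants.

source("analysis/00_config.R")

counts <- read_tsv_file(file.path(OUT, "counts_oligo.tsv"))
oligo_counts <- as.matrix(counts[, -1]); rownames(oligo_counts) <- counts[[1]]
samples <- read_tsv_file(file.path(OUT, "samples.tsv"))
variants <- read_tsv_file(file.path(OUT, "variants.tsv"))
vclasses <- read_tsv_file(file.path(OUT, "variant_classes.tsv"))
au <- read_tsv_file(file.path(OUT, "allelic_union.tsv"))

qc <- replicate_qc(oligo_counts, samples)
write_tsv_file(data.frame(sample_id = rownames(qc$correlation),
                          qc$correlation, check.names = FALSE),
               file.path(OUT, "replicate_correlation.tsv"))
write_tsv_file(qc$assignment, file.path(OUT, "replicate_clusters.tsv"))

loci <- summarize_loci(vclasses, au, variants[, c("variant_id", "locus_id")])
write_tsv_file(loci$table, file.path(OUT, "locus_summary.tsv"))

off <- qc$correlation[upper.tri(qc$correlation)]
cat(sprintf(paste0(
  "Replicate QC: median between-sample correlation %.3f; ",
  "replicates cluster by annotated group: %s.\n"),
  median(off, na.rm = TRUE), qc$clusters_by_group))
cat(sprintf(paste0(
  "Loci: %d of %d with regulatory activity ",
  "(median %.0f enhancer / %.0f silencer variants per active locus);\n",
  "allelic activity at %d loci, %d loci with both allelic classes.\n"),
  loci$n_loci_regulatory, nrow(loci$table),
  loci$medians["enhancer"], loci$medians["silencer"],
  loci$n_loci_allelic, loci$n_loci_both_allelic))
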