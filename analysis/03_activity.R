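# Stage 3: enhancer/silencer calling. NB differential test of each cell
# line's RNA replicates against the plasmid controls, BH correction, the
# 1.2-fold rule, variant rollup, and comparison against the planted truth.

source("analysis/00_config.R")

th <- study_thresholds()
counts <- read_tsv_file(file.path(OUT, "counts_oligo.tsv"))
oligo_counts <- as.matrix(counts[, -1]); rownames(oligo_counts) <- counts[[1]]
samples <- read_tsv_file(file.path(OUT, "samples.tsv"))
designs <- read_tsv_file(file.path(OUT, "design.tsv"))
nbc_tab <- read_tsv_file(file.path(OUT, "plasmid_barcodes.tsv"))
nbc <- setNames(nbc_tab$n_plasmid_barcodes, nbc_tab$oligo_id)
truth <- read_tsv_file(file.path(OUT, "truth_variant.tsv"))

activity <- do.call(rbind, lapply(cell_lines(samples), function(cl)
  call_activity(oligo_counts, samples, designs, cl,
                n_plasmid_barcodes = nbc, thresholds = th)))
write_tsv_file(activity, file.path(OUT, "activity.tsv"))
for (cl in unique(activity$cell_line)) {
  a <- activity[activity$cell_line == cl, ]
  write_tsv_file(data.frame(unit_id = a$unit_id, log2fc = a$log2fc,
                            neg_log10_padj = -log10(pmax(a$padj, 1e-300)),
                            class = a$activity_class),
                 file.path(OUT, paste0("volcano_", cl, ".tsv")))
}
roll <- rollup_variants(activity)
write_tsv_file(roll$variant_classes, file.path(OUT, "variant_classes.tsv"))
write_tsv_file(roll$contradictory, file.path(OUT, "contradictory.tsv"))

vc <- roll$variant_classes
for (cl in unique(vc$cell_line)) {
  v <- vc[vc$cell_line == cl, ]
  cat(sprintf("%s: %d enhancer and %d silencer variants\n",
              cl, sum(v$enhancer), sum(v$silencer)))
}
enh_u <- unique(vc$variant_id[vc$enhancer])
sil_u <- unique(vc$variant_id[vc$silencer])
enh_t <- truth$variant_id[truth$class == "enhancer"]
sil_t <- truth$variant_id[truth$class == "silencer"]
cat(sprintf(paste0(
  "Across cell lines (union): %d enhancer, %d silencer variants;\n",
  "sensitivity vs planted truth: enhancers %.2f, silencers %.2f;\n",
  "false-positive variants among neutrals: %d; contradictory calls: %d.\n"),
  length(enh_u), length(sil_u),
  mean(enh_t %in% enh_u), mean(sil_t %in% sil_u),
  sum(!(union(enh_u, sil_u) %in% union(enh_t, sil_t))),
  nrow(roll$contradictory)))
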