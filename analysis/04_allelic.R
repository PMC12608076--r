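# Stage 4: allelic calling. Among regulatory variants, Student's t-test of
# per-replicate log2 nonreference/reference count ratios in RNA vs plasmid
# replicates, the 20% effect threshold, and the cross-cell-line union.

source("analysis/00_config.R")

th <- study_thresholds()
counts <- read_tsv_file(file.path(OUT, "counts_oligo.tsv"))
oligo_counts <- as.matrix(counts[, -1]); rownames(oligo_counts) <- counts[[1]]
samples <- read_tsv_file(file.path(OUT, "samples.tsv"))
designs <- read_tsv_file(file.path(OUT, "design.tsv"))
activity <- read_tsv_file(file.path(OUT, "activity.tsv"))
vclasses <- read_tsv_file(file.path(OUT, "variant_classes.tsv"))
contra <- read_tsv_file(file.path(OUT, "contradictory.tsv"))
truth <- read_tsv_file(file.path(OUT, "truth_variant.tsv"))

allelic <- do.call(rbind, lapply(cell_lines(samples), function(cl)
  call_allelic(oligo_counts, samples, designs, activity, vclasses, contra,
               cl, thresholds = th)))
write_tsv_file(allelic, file.path(OUT, "allelic.tsv"))
su <- summarize_allelic(allelic)
write_tsv_file(su$union, file.path(OUT, "allelic_union.tsv"))

for (cl in unique(allelic$cell_line)) {
  a <- allelic[allelic$cell_line == cl, ]
  cat(sprintf("%s: %d allelic enhancer, %d allelic silencer variants (%d pairs tested)\n",
              cl, length(unique(a$variant_id[a$allelic_class == "allelic_enhancer"])),
              length(unique(a$variant_id[a$allelic_class == "allelic_silencer"])),
              nrow(a)))
}
called <- su$union$variant_id
planted <- truth$variant_id[truth$allelic]
cat(sprintf(paste0(
  "Union across cell lines: %d allelic variants ",
  "(%d planted; %.2f of planted recovered; %d calls on non-allelic variants).\n"),
  length(called), length(planted),
  mean(planted %in% called), sum(!(called %in% planted))))
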