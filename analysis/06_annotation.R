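# Stage 6: target-gene annotation. Direction-matched eQTL records connect
# allelic variants to genes; gene lists are tested for over-representation
# in (simulated) gene sets.

source("analysis/00_config.R")

th <- study_thresholds()
cfg <- study_config()
allelic <- read_tsv_file(file.path(OUT, "allelic.tsv"))
eqtl <- read_tsv_file(file.path(OUT, "eqtl.tsv"))

ann <- annotate_genes(allelic, eqtl, tissue = "LCL", thresholds = th)
write_tsv_file(ann$pairs, file.path(OUT, "variant_genes.tsv"))

universe <- unique(eqtl$gene)
gmt_path <- file.path(OUT, "gene_sets.gmt")
sets <- simulate_gene_sets(universe,
                           target = unique(unlist(ann$genes)),
                           n_sets = 10L, set_size = 50L, seed = cfg$seed)
write_gmt(sets, gmt_path)
sets <- read_gmt(gmt_path)

cat(sprintf("Annotated %d variant-gene pairs (%d allele-mismatch rows dropped).\n",
            nrow(ann$pairs), ann$n_allele_mismatch))
for (cls in names(ann$genes)) {
  ora <- overrepresentation(ann$genes[[cls]], sets, universe)
  write_tsv_file(ora, file.path(OUT, paste0("ora_", cls, ".tsv")))
  top <- ora[1, ]
  cat(sprintf("  %-17s %3d genes; top set %-12s overlap %2d, p %.2e, padj %.2e%s\n",
              cls, length(ann$genes[[cls]]), top$gene_set, top$overlap,
              top$p, top$padj,
              if (top$below_display_threshold) " (below display threshold)" else ""))
}
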