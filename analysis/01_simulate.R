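# Stage 1: generate the synthetic MPRA study — variant records, oligo
# designs, the ground-truth barcode map, planted effects, barcode-level
# count matrices, ChIP-seq-style peak datasets and an eQTL table.

source("analysis/00_config.R")

cfg <- study_config()
lib <- simulate_library(cfg)
sim <- simulate_counts(lib, cfg)
pe <- simulate_peaks_eqtls(lib, enriched_frac = 0.8, background_frac = 0.1,
                           n_background = 3L, sign_consistency = 1)

write_tsv_file(lib$variants, file.path(OUT, "variants.tsv"))
write_tsv_file(lib$designs[, c("oligo_id", "variant_id", "allele",
                               "allele_role", "orientation", "full")],
               file.path(OUT, "design.tsv"))
write_fasta(setNames(lib$designs$full, lib$designs$oligo_id),
            file.path(OUT, "design.fasta"))
write_tsv_file(lib$barcode_map, file.path(OUT, "truth_barcode_map.tsv"))
write_tsv_file(lib$truth$oligo, file.path(OUT, "truth_oligo.tsv"))
write_tsv_file(lib$truth$variant, file.path(OUT, "truth_variant.tsv"))
write_tsv_file(data.frame(barcode = rownames(sim$counts), sim$counts,
                          check.names = FALSE),
               file.path(OUT, "counts_barcode.tsv"))
write_tsv_file(sim$samples, file.path(OUT, "samples.tsv"))
write_tsv_file(pe$eqtl, file.path(OUT, "eqtl.tsv"))
for (nm in names(pe$peaks))
  write_bed(pe$peaks[[nm]], file.path(OUT, paste0("peaks_", nm, ".bed")))
jsonlite::write_json(unclass(cfg), file.path(OUT, "config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

tv <- lib$truth$variant
cat(sprintf(paste0(
  "Simulated study: %d variants (%d loci), %d oligos, %d barcodes.\n",
  "Planted: %d enhancer, %d silencer variants; %d with allelic effects.\n",
  "Samples: %d plasmid + %d RNA replicates across %d cell lines.\n"),
  nrow(lib$variants), cfg$n_loci, nrow(lib$designs), nrow(lib$barcode_map),
  sum(tv$class == "enhancer"), sum(tv$class == "silencer"), sum(tv$allelic),
  cfg$n_plasmid_reps, cfg$n_rna_reps * cfg$n_cell_lines, cfg$n_cell_lines))
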