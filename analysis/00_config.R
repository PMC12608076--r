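# Shared configuration for the analysis workflow. Each numbered script is a
# thin driver over the mpracall package; run them in order from the
# repository root:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_associate_quantify.R
#   ...
#
# Desk-scale study: 500 variants across 50 loci, three cell lines, five
# plasmid and five RNA replicates per line, with planted enhancer, silencer
# and allelic effects. Outputs accumulate under results/analysis/.

suppressMessages(library(mpracall))

OUT <- "results/analysis"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

study_config <- function(seed = 20260901L) {
  sim_config(n_variants = 500, n_loci = 50,
             barcodes_per_oligo_median = 60,
             depth_per_sample = 1.5e5, n_cell_lines = 3,
             frac_enhancer = 0.08, frac_silencer = 0.15,
             frac_allelic_given_regulatory = 0.13,
             seed = seed)
}

study_thresholds <- function() default_thresholds()

# cell lines of the study
cell_lines <- function(samples) unique(samples$cell_line[samples$role == "rna"])
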