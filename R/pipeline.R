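# Orchestration: replicate QC, per-locus summaries, and an end-to-end driver
# that runs every stage on a simulated study and writes TSV artifacts with a
# JSON provenance manifest.

#' Replicate quality control
#'
#' Pearson correlations between samples on log2 size-factor-normalized oligo
#' counts, with average-linkage hierarchical clustering on 1 - r. Reports
#' whether samples cluster by their annotated group (cell line / plasmid).
#'
#' @param oligo_counts oligo-level count matrix.
#' @param samples sample sheet (sample_id, role, cell_line).
#' @param pseudocount added before the log.
#' @return list(correlation = matrix (constant columns give NA), hclust,
#'   assignment = data.frame(sample_id, group, cluster), clusters_by_group =
#'   logical).
#' @export
replicate_qc <- function(oligo_counts, samples, pseudocount = 1) {
  if (ncol(oligo_counts) < 2L) stop("need >= 2 samples for replicate QC")
  sf <- size_factors(oligo_counts)
  lg <- log2(sweep(oligo_counts, 2L, sf, "/") + pseudocount)
  constant <- apply(lg, 2L, function(x) sd(x) == 0)
  cm <- suppressWarnings(cor(lg, method = "pearson"))
  cm[constant, ] <- NA_real_
  cm[, constant] <- NA_real_
  diag(cm) <- 1
  group <- ifelse(samples$role == "plasmid", "plasmid", samples$cell_line)
  group <- group[match(colnames(oligo_counts), samples$sample_id)]
  usable <- !constant
  hc <- NULL; cl <- rep(NA_integer_, ncol(lg))
  by_group <- NA
  if (sum(usable) >= 2L) {
    d <- as.dist(1 - cm[usable, usable, drop = FALSE])
    hc <- hclust(d, method = "average")
    k <- length(unique(group[usable]))
    cl[usable] <- cutree(hc, k = max(1L, min(k, sum(usable))))
    tab <- table(group[usable], cl[usable])
    # each group maps into a single cluster and clusters don't mix groups
    by_group <- all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
  }
  list(correlation = cm, hclust = hc,
       assignment = data.frame(sample_id = colnames(oligo_counts),
                               group = group, cluster = cl,
                               stringsAsFactors = FALSE),
       clusters_by_group = by_group)
}

#' Per-locus summary of regulatory and allelic regulatory variants
#'
#' Counts, per independent risk locus, the variants classed enhancer /
#' silencer / allelic enhancer / allelic silencer (union across cell lines).
#' Histogram tables exclude loci with zero counts of the summarized class;
#' medians are taken over the included loci.
#'
#' @param variant_classes from [rollup_variants()].
#' @param allelic_union union table from [summarize_allelic()].
#' @param variant_loci data.frame(variant_id, locus_id).
#' @return list(table = data.frame(locus_id, n_enhancer_variants,
#'   n_silencer_variants, n_allelic_enhancer, n_allelic_silencer, has_both),
#'   medians = named numeric, n_loci_regulatory, n_loci_allelic,
#'   n_loci_both_allelic).
#' @export
summarize_loci <- function(variant_classes, allelic_union, variant_loci) {
  locus_of <- setNames(variant_loci$locus_id, variant_loci$variant_id)
  get_locus <- function(v) {
    l <- unname(locus_of[v])
    if (anyNA(l)) {
      warning(sum(is.na(l)), " variants with no locus; counted as 'unassigned'")
      l[is.na(l)] <- "unassigned"
    }
    l
  }
  enh_v <- unique(variant_classes$variant_id[variant_classes$enhancer])
  sil_v <- unique(variant_classes$variant_id[variant_classes$silencer])
  ae_v <- allelic_union$variant_id[allelic_union$allelic_enhancer]
  as_v <- allelic_union$variant_id[allelic_union$allelic_silencer]

  loci <- sort(unique(variant_loci$locus_id))
  cnt <- function(v) {
    t <- table(factor(get_locus(v), levels = loci))
    as.integer(t)
  }
  tab <- data.frame(locus_id = loci,
                    n_enhancer_variants = cnt(enh_v),
                    n_silencer_variants = cnt(sil_v),
                    n_allelic_enhancer = cnt(ae_v),
                    n_allelic_silencer = cnt(as_v),
                    stringsAsFactors = FALSE)
  tab$has_both <- tab$n_enhancer_variants > 0 & tab$n_silencer_variants > 0
  med <- function(x) if (any(x > 0)) median(x[x > 0]) else NA_real_
  list(table = tab,
       medians = c(enhancer = med(tab$n_enhancer_variants),
                   silencer = med(tab$n_silencer_variants),
                   allelic_enhancer = med(tab$n_allelic_enhancer),
                   allelic_silencer = med(tab$n_allelic_silencer)),
       n_loci_regulatory = sum(tab$n_enhancer_variants > 0 |
                                 tab$n_silencer_variants > 0),
       n_loci_allelic = sum(tab$n_allelic_enhancer > 0 |
                              tab$n_allelic_silencer > 0),
       n_loci_both_allelic = sum(tab$n_allelic_enhancer > 0 &
                                   tab$n_allelic_silencer > 0))
}

# write a TSV plus a sidecar provenance JSON block
.write_artifact <- function(x, path, manifest, stage, inputs = character(0)) {
  write_tsv_file(x, path)
  manifest$files[[basename(path)]] <- list(
    path = path, stage = stage, inputs = inputs,
    md5 = unname(tools::md5sum(path)), rows = nrow(x))
  manifest
}

#' Run the full synthetic MPRA analysis end to end
#'
#' Stages, in dependency order: simulate (library, truth, counts, peaks,
#' eQTLs), associate (paired-end reads to a recovered barcode map), quantify
#' (tag reads to count tables), activity (per cell line), allelic, reli,
#' annotate, report (replicate QC and locus summaries). Stage toggles allow
#' skipping the read-level stages, in which case the simulator's counts and
#' truth map feed the callers directly. All tables are TSV; a JSON manifest
#' records inputs, seed, thresholds and file checksums.
#'
#' @param config from [sim_config()].
#' @param out_dir output directory (created).
#' @param thresholds from [default_thresholds()].
#' @param use_reads run the read-level association/quantification stages
#'   (slower) instead of using the simulator's count table directly.
#' @param reads_per_barcode association read pairs per barcode (read stage).
#' @param enriched_frac,background_frac,n_background,sign_consistency
#'   passed to [simulate_peaks_eqtls()].
#' @return list with all in-memory results and `manifest` (also written to
#'   manifest.json).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         thresholds = default_thresholds(),
                         use_reads = FALSE, reads_per_barcode = 3L,
                         enriched_frac = 0.8, background_frac = 0.1,
                         n_background = 3L, sign_consistency = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new.env()
  manifest$files <- list()
  manifest$seed <- config$seed
  manifest$thresholds <- thresholds

  # --- simulate ---------------------------------------------------------
  lib <- simulate_library(config)
  sim <- simulate_counts(lib, config, level = "barcode")
  pe <- simulate_peaks_eqtls(lib, enriched_frac = enriched_frac,
                             background_frac = background_frac,
                             n_background = n_background,
                             sign_consistency = sign_consistency)
  manifest <- .write_artifact(lib$variants, file.path(out_dir, "variants.tsv"),
                              manifest, "simulate")
  manifest <- .write_artifact(
    lib$designs[, c("oligo_id", "variant_id", "allele", "allele_role",
                    "orientation", "full")],
    file.path(out_dir, "design.tsv"), manifest, "simulate")
  manifest <- .write_artifact(lib$truth$oligo,
                              file.path(out_dir, "truth_oligo.tsv"),
                              manifest, "simulate")
  manifest <- .write_artifact(lib$truth$variant,
                              file.path(out_dir, "truth_variant.tsv"),
                              manifest, "simulate")
  manifest <- .write_artifact(pe$eqtl, file.path(out_dir, "eqtl.tsv"),
                              manifest, "simulate")
  for (nm in names(pe$peaks))
    write_bed(pe$peaks[[nm]], file.path(out_dir, paste0("peaks_", nm, ".bed")))

  # --- associate / quantify --------------------------------------------
  if (use_reads) {
    rd <- simulate_association_reads(lib, reads_per_barcode = reads_per_barcode)
    idx <- build_oligo_index(lib$designs)
    asc <- associate_barcodes(rd$read1, rd$read2, idx)
    map <- build_barcode_map(asc$associations)$map
    bc_counts <- matrix(0L, nrow = nrow(map), ncol = nrow(sim$samples),
                        dimnames = list(map$barcode, sim$samples$sample_id))
    for (s in sim$samples$sample_id) {
      reads <- simulate_tag_reads(lib, sim$counts, s)
      bc_counts[, s] <- quantify_sample(reads, map)$counts
    }
  } else {
    map <- lib$barcode_map
    map$support_reads <- reads_per_barcode
    map$purity <- 1
    bc_counts <- sim$counts
  }
  manifest <- .write_artifact(map, file.path(out_dir, "barcode_map.tsv"),
                              manifest, "associate", "design.tsv")
  st <- map_stats(map, lib$designs$oligo_id)
  agg <- aggregate_to_oligo(bc_counts, map, lib$designs$oligo_id)
  oligo_counts <- agg$counts
  manifest <- .write_artifact(
    data.frame(oligo_id = rownames(oligo_counts), oligo_counts,
               check.names = FALSE),
    file.path(out_dir, "counts_oligo.tsv"), manifest, "quantify",
    "barcode_map.tsv")

  # --- activity ---------------------------------------------------------
  nbc <- plasmid_barcode_count(bc_counts, map, sim$samples)
  cls <- unique(sim$samples$cell_line[sim$samples$role == "rna"])
  activity <- do.call(rbind, lapply(cls, function(c_)
    call_activity(oligo_counts, sim$samples, lib$designs, c_,
                  n_plasmid_barcodes = nbc, thresholds = thresholds)))
  roll <- rollup_variants(activity)
  for (c_ in cls) {
    a <- activity[activity$cell_line == c_, , drop = FALSE]
    manifest <- .write_artifact(a, file.path(out_dir,
      paste0("activity_", c_, ".tsv")), manifest, "activity",
      "counts_oligo.tsv")
    volcano <- data.frame(unit_id = a$unit_id, log2fc = a$log2fc,
                          neg_log10_padj = -log10(pmax(a$padj, 1e-300)),
                          class = a$activity_class, stringsAsFactors = FALSE)
    manifest <- .write_artifact(volcano, file.path(out_dir,
      paste0("volcano_", c_, ".tsv")), manifest, "activity")
  }
  manifest <- .write_artifact(roll$variant_classes,
                              file.path(out_dir, "variant_classes.tsv"),
                              manifest, "activity")

  # --- allelic ----------------------------------------------------------
  allelic <- do.call(rbind, lapply(cls, function(c_)
    call_allelic(oligo_counts, sim$samples, lib$designs, activity,
                 roll$variant_classes, roll$contradictory, c_,
                 thresholds = thresholds)))
  al_sum <- summarize_allelic(allelic)
  manifest <- .write_artifact(allelic, file.path(out_dir, "allelic.tsv"),
                              manifest, "allelic", "variant_classes.tsv")
  manifest <- .write_artifact(al_sum$union,
                              file.path(out_dir, "allelic_union.tsv"),
                              manifest, "allelic")

  # --- reli -------------------------------------------------------------
  enh_v <- unique(roll$variant_classes$variant_id[roll$variant_classes$enhancer])
  sil_v <- unique(roll$variant_classes$variant_id[roll$variant_classes$silencer])
  input_sets <- list(enhancer = enh_v, silencer = sil_v)
  if (nrow(al_sum$union)) {
    input_sets$allelic_enhancer <-
      al_sum$union$variant_id[al_sum$union$allelic_enhancer]
    input_sets$allelic_silencer <-
      al_sum$union$variant_id[al_sum$union$allelic_silencer]
  }
  input_sets <- input_sets[vapply(input_sets, length, integer(1)) > 0L]
  reli <- NULL
  if (length(input_sets)) {
    reli <- run_battery(input_sets, lib$variants$variant_id, lib$variants,
                        pe$peaks, iterations = thresholds$reli_iterations,
                        seed = config$seed)
    manifest <- .write_artifact(reli, file.path(out_dir, "reli.tsv"),
                                manifest, "reli", "variant_classes.tsv")
  }

  # --- annotate ---------------------------------------------------------
  ann <- annotate_genes(allelic, pe$eqtl, tissue = "LCL",
                        thresholds = thresholds)
  manifest <- .write_artifact(ann$pairs,
                              file.path(out_dir, "variant_genes.tsv"),
                              manifest, "annotate", "allelic.tsv")
  universe <- unique(pe$eqtl$gene)
  ora <- list()
  for (cl_ in names(ann$genes)) {
    sets <- simulate_gene_sets(universe, target = ann$genes[[cl_]],
                               seed = config$seed)
    ora[[cl_]] <- overrepresentation(ann$genes[[cl_]], sets, universe)
    manifest <- .write_artifact(ora[[cl_]], file.path(out_dir,
      paste0("ora_", cl_, ".tsv")), manifest, "annotate")
  }

  # --- report -----------------------------------------------------------
  qc <- replicate_qc(oligo_counts, sim$samples)
  loci <- summarize_loci(roll$variant_classes, al_sum$union,
                         lib$variants[, c("variant_id", "locus_id")])
  manifest <- .write_artifact(loci$table,
                              file.path(out_dir, "locus_summary.tsv"),
                              manifest, "report")
  manifest <- .write_artifact(
    data.frame(sample_id = rownames(qc$correlation), qc$correlation,
               check.names = FALSE),
    file.path(out_dir, "replicate_correlation.tsv"), manifest, "report")

  man <- list(seed = config$seed,
              thresholds = thresholds,
              config = unclass(config),
              median_barcodes_per_oligo = st$median_observed,
              clusters_by_group = qc$clusters_by_group,
              files = manifest$files)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(library = lib, counts = sim, map = map,
                 oligo_counts = oligo_counts, activity = activity,
                 rollup = roll, allelic = allelic, allelic_union = al_sum,
                 reli = reli, annotation = ann, ora = ora, qc = qc,
                 loci = loci, manifest = man))
}
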