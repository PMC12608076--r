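# Synthetic MPRA study generator. Produces variants, oligo libraries,
# barcode maps, sequencing reads, count matrices, peak files and eQTL tables
# with known planted enhancer / silencer / allelic effects, so every
# downstream stage can be validated against ground truth.

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Defaults emulate the structure of the emulated assay: a multi-allele
#' library with a mean of 2.7 alleles per variant and a median of 239 unique
#' barcodes per oligo, 5 plasmid replicates and 5 RNA replicates in each of
#' 3 cell lines. Library size defaults to a desk-scale 500 variants.
#'
#' @param n_variants number of variants.
#' @param alleles_per_variant_mean mean alleles per variant (in [2, 4)).
#' @param n_loci independent risk loci (each its own synthetic chromosome
#'   chrS1..chrSn).
#' @param barcodes_per_oligo_median median unique barcodes per oligo.
#' @param barcode_lognorm_sdlog log-sd of the log-normal barcode-count
#'   distribution around the median.
#' @param n_plasmid_reps,n_rna_reps,n_cell_lines replicate structure.
#' @param depth_per_sample reads per sample for count simulation.
#' @param nb_dispersion shared NB dispersion of the counts.
#' @param frac_enhancer,frac_silencer fractions of variants planted as
#'   enhancers / silencers.
#' @param frac_allelic_given_regulatory fraction of regulatory variants with
#'   a planted allelic effect.
#' @param effect_fc_range_enh,effect_fc_range_sil fold-change intervals of
#'   planted effects (enhancers > 1.2, silencers < 1/1.2).
#' @param allelic_ratio_range interval of planted nonref/ref activity ratios
#'   (>= 1.2; direction randomized).
#' @param seed integer master seed; every generator derives stage seeds from
#'   it deterministically.
#' @return validated config list.
#' @export
sim_config <- function(n_variants = 500L,
                       alleles_per_variant_mean = 2.7,
                       n_loci = 50L,
                       barcodes_per_oligo_median = 239L,
                       barcode_lognorm_sdlog = 0.5,
                       n_plasmid_reps = 5L,
                       n_rna_reps = 5L,
                       n_cell_lines = 3L,
                       depth_per_sample = 2e6,
                       nb_dispersion = 0.05,
                       frac_enhancer = 0.08,
                       frac_silencer = 0.15,
                       frac_allelic_given_regulatory = 0.13,
                       effect_fc_range_enh = c(1.5, 3),
                       effect_fc_range_sil = c(1 / 3, 1 / 1.5),
                       allelic_ratio_range = c(1.3, 2),
                       seed = 1L) {
  cfg <- list(n_variants = as.integer(n_variants),
              alleles_per_variant_mean = alleles_per_variant_mean,
              n_loci = as.integer(n_loci),
              barcodes_per_oligo_median = as.integer(barcodes_per_oligo_median),
              barcode_lognorm_sdlog = barcode_lognorm_sdlog,
              n_plasmid_reps = as.integer(n_plasmid_reps),
              n_rna_reps = as.integer(n_rna_reps),
              n_cell_lines = as.integer(n_cell_lines),
              depth_per_sample = depth_per_sample,
              nb_dispersion = nb_dispersion,
              frac_enhancer = frac_enhancer,
              frac_silencer = frac_silencer,
              frac_allelic_given_regulatory = frac_allelic_given_regulatory,
              effect_fc_range_enh = effect_fc_range_enh,
              effect_fc_range_sil = effect_fc_range_sil,
              allelic_ratio_range = allelic_ratio_range,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_variants > 0, n_loci > 0, barcodes_per_oligo_median > 0,
              n_plasmid_reps > 0, n_rna_reps > 0, n_cell_lines > 0,
              depth_per_sample > 0, nb_dispersion > 0,
              frac_enhancer >= 0, frac_enhancer <= 1,
              frac_silencer >= 0, frac_silencer <= 1,
              frac_enhancer + frac_silencer <= 1,
              frac_allelic_given_regulatory >= 0,
              frac_allelic_given_regulatory <= 1,
              alleles_per_variant_mean >= 2,
              alleles_per_variant_mean < 4,
              all(effect_fc_range_enh >= 1.2),
              all(effect_fc_range_sil <= 1 / 1.2),
              all(allelic_ratio_range >= 1.2))
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Draw alleles-per-variant counts
#'
#' Counts are 2 plus a Poisson excess truncated at 2 (so 2..4 alleles), with
#' the Poisson rate solved so the expectation equals `mean`.
#'
#' @param n number of variants.
#' @param mean target mean alleles per variant (in [2, 4)).
#' @return integer vector in 2..4. Uses the current RNG state.
#' @export
sample_allele_counts <- function(n, mean = 2.7) {
  stopifnot(mean >= 2, mean < 4)
  target <- mean - 2
  if (target == 0) return(rep(2L, n))
  # E[min(Pois(l), 2)] = 2 - 2 exp(-l) - l exp(-l)
  lambda <- uniroot(function(l) 2 - 2 * exp(-l) - l * exp(-l) - target,
                    c(1e-9, 50))$root
  2L + pmin(rpois(n, lambda), 2L)
}

# fast random DNA via column-wise paste
.random_dna_fast <- function(n, len) {
  if (n == 0L) return(character(0))
  cols <- replicate(len, sample(DNA_BASES, n, replace = TRUE),
                    simplify = FALSE)
  do.call(paste0, cols)
}

# n unique random 20-mers
.unique_barcodes <- function(n) {
  if (n > 4^20) stop("requested more barcodes than 4^20 distinct 20-mers")
  bc <- .random_dna_fast(n, BARCODE_LEN)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- .random_dna_fast(length(dup), BARCODE_LEN)
  }
  bc
}

#' Simulate an MPRA oligo library with planted effects
#'
#' Generates variant records on synthetic chromosomes (one per locus),
#' genomic flanks, forward/reverse-complement oligo designs through the
#' design operations, a ground-truth barcode map, and a truth table of
#' planted per-variant classes, fold changes and allelic ratios.
#'
#' @param config from [sim_config()].
#' @return list: variants, flanks, designs, barcode_map (data.frame barcode,
#'   oligo_id), truth (list oligo/variant data.frames), config.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "library"), {
    n <- config$n_variants
    n_all <- sample_allele_counts(n, config$alleles_per_variant_mean)
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alts <- vapply(seq_len(n), function(i)
      paste(sample(setdiff(DNA_BASES, ref[i]), n_all[i] - 1L),
            collapse = ","), character(1))
    locus <- sprintf("L%03d", rep_len(seq_len(config$n_loci), n))
    within_locus <- ave(seq_len(n), locus, FUN = seq_along)
    variants <- data.frame(
      variant_id = sprintf("rs%06d", seq_len(n)),
      chrom = paste0("chrS", as.integer(sub("^L", "", locus))),
      pos = 100000L + within_locus * 500L,
      ref_allele = ref,
      alt_alleles = alts,
      locus_id = locus,
      tier = sample(c("genome_wide", "suggestive"), n, replace = TRUE,
                    prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)

    flanks <- setNames(lapply(seq_len(n), function(i)
      list(up = .random_dna_fast(1L, SNP_UP),
           down = .random_dna_fast(1L, SNP_DOWN))),
      variants$variant_id)

    kept <- filter_variants(variants)$kept
    em <- emit_oligos(kept, flanks)
    designs <- em$designs

    # planted variant classes and effects
    u <- runif(n)
    class <- ifelse(u < config$frac_enhancer, "enhancer",
                    ifelse(u < config$frac_enhancer + config$frac_silencer,
                           "silencer", "neutral"))
    fc <- rep(1, n)
    enh <- class == "enhancer"; sil <- class == "silencer"
    fc[enh] <- runif(sum(enh), config$effect_fc_range_enh[1L],
                     config$effect_fc_range_enh[2L])
    fc[sil] <- runif(sum(sil), config$effect_fc_range_sil[1L],
                     config$effect_fc_range_sil[2L])
    reg <- class != "neutral"
    allelic <- reg & runif(n) < config$frac_allelic_given_regulatory
    ratio <- rep(1, n)
    r <- runif(sum(allelic), config$allelic_ratio_range[1L],
               config$allelic_ratio_range[2L])
    flip <- runif(sum(allelic)) < 0.5
    ratio[allelic] <- ifelse(flip, 1 / r, r)

    first_alt <- vapply(strsplit(variants$alt_alleles, ",", fixed = TRUE),
                        `[[`, character(1), 1L)
    truth_variant <- data.frame(
      variant_id = variants$variant_id,
      locus_id = variants$locus_id,
      class = class, fc = fc,
      allelic = allelic, allelic_ratio = ratio,
      log2_allelic = log2(ratio),
      ref_allele = variants$ref_allele,
      nonref_allele = first_alt,
      stringsAsFactors = FALSE)

    vi <- match(designs$variant_id, variants$variant_id)
    nonref <- designs$allele_role != "Ref"
    activity <- fc[vi] * ifelse(nonref, ratio[vi], 1)
    truth_oligo <- data.frame(
      oligo_id = designs$oligo_id,
      variant_id = designs$variant_id,
      allele = designs$allele,
      allele_role = designs$allele_role,
      orientation = designs$orientation,
      class = class[vi],
      fc = fc[vi],
      activity = activity,
      stringsAsFactors = FALSE)

    # ground-truth barcode map: log-normal barcode counts around the median
    nbc <- pmax(1L, as.integer(round(rlnorm(nrow(designs),
      meanlog = log(config$barcodes_per_oligo_median),
      sdlog = config$barcode_lognorm_sdlog))))
    bc <- .unique_barcodes(sum(nbc))
    barcode_map <- data.frame(
      barcode = bc,
      oligo_id = rep(designs$oligo_id, nbc),
      stringsAsFactors = FALSE)

    list(variants = variants, flanks = flanks, designs = designs,
         barcode_map = barcode_map,
         truth = list(oligo = truth_oligo, variant = truth_variant),
         config = config)
  })
}

#' Sample sheet for a simulated study
#'
#' @param config from [sim_config()].
#' @return data.frame(sample_id, role, cell_line, replicate).
#' @export
sim_sample_sheet <- function(config) {
  cl <- sprintf("CL%d", seq_len(config$n_cell_lines))
  rbind(
    data.frame(sample_id = sprintf("plasmid_%d", seq_len(config$n_plasmid_reps)),
               role = "plasmid", cell_line = "plasmid",
               replicate = seq_len(config$n_plasmid_reps),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(cl, function(c_)
      data.frame(sample_id = sprintf("rna_%s_%d", c_, seq_len(config$n_rna_reps)),
                 role = "rna", cell_line = c_,
                 replicate = seq_len(config$n_rna_reps),
                 stringsAsFactors = FALSE))))
}

#' Simulate plasmid and RNA count matrices
#'
#' Plasmid counts are NB around per-barcode abundances (log-normal library
#' composition) scaled to the sample depth; RNA counts are NB around the
#' same abundances multiplied by each oligo's planted activity (fold change,
#' times the allelic ratio for nonreference alleles) and rescaled to depth,
#' so relative fold changes are preserved and column totals are conserved.
#'
#' @param library from [simulate_library()].
#' @param config from [sim_config()].
#' @param level `"barcode"` (default) simulates per-barcode counts;
#'   `"oligo"` simulates directly at oligo level (rows = oligo ids).
#' @param cell_line_effect_sd optional log-normal sd of cell-line-specific
#'   activity jitter (0 = identical effects in all lines).
#' @return list(counts = integer matrix with rownames, samples = sample
#'   sheet).
#' @export
simulate_counts <- function(library, config = library$config,
                            level = c("barcode", "oligo"),
                            cell_line_effect_sd = 0) {
  level <- match.arg(level)
  samples <- sim_sample_sheet(config)
  with_seed(child_seed(config$seed, paste0("counts_", level)), {
    if (level == "barcode") {
      ids <- library$barcode_map$barcode
      oligo_of <- library$barcode_map$oligo_id
    } else {
      ids <- library$designs$oligo_id
      oligo_of <- ids
    }
    act <- library$truth$oligo$activity[
      match(oligo_of, library$truth$oligo$oligo_id)]
    abund <- rlnorm(length(ids), 0, 1)
    size <- 1 / config$nb_dispersion
    counts <- matrix(0L, nrow = length(ids), ncol = nrow(samples),
                     dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      if (samples$role[j] == "plasmid") {
        mu <- abund / sum(abund) * config$depth_per_sample
      } else {
        a <- act
        if (cell_line_effect_sd > 0) {
          # line-specific activity jitter, shared by all barcodes of an
          # oligo and by all replicates of the line
          cl_seed <- child_seed(config$seed,
                                paste0("cl_", samples$cell_line[j]))
          jit_oligo <- with_seed(cl_seed,
            rlnorm(nrow(library$designs), 0, cell_line_effect_sd))
          a <- a * jit_oligo[match(oligo_of, library$designs$oligo_id)]
        }
        w <- abund * a
        mu <- w / sum(w) * config$depth_per_sample
      }
      counts[, j] <- as.integer(rnbinom(length(ids), mu = mu, size = size))
    }
    list(counts = counts, samples = samples)
  })
}

# per-base substitution errors on a vector of reads
.add_read_errors <- function(seqs, error_rate) {
  if (error_rate == 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end association reads
#'
#' Read 1 is the 20-bp barcode followed by the 5' end of the full oligo;
#' read 2 reads the 3' end of the oligo (reverse strand). Every barcode in
#' the map is emitted `reads_per_barcode` times.
#'
#' @param library from [simulate_library()].
#' @param reads_per_barcode read pairs emitted per barcode.
#' @param error_rate per-base substitution rate (in [0, 0.2]).
#' @param read_len read length for both mates.
#' @param qual_char quality character applied to every base.
#' @return list(read1, read2) of data.frames(id, seq, qual).
#' @export
simulate_association_reads <- function(library, reads_per_barcode = 3L,
                                       error_rate = 0, read_len = 150L,
                                       qual_char = "I") {
  if (error_rate < 0 || error_rate > 0.2)
    stop("error_rate must be in [0, 0.2]")
  config <- library$config
  with_seed(child_seed(config$seed, "assoc_reads"), {
    full <- library$designs$full[
      match(library$barcode_map$oligo_id, library$designs$oligo_id)]
    region_len <- read_len - BARCODE_LEN
    r1 <- paste0(library$barcode_map$barcode, substr(full, 1L, region_len))
    r2 <- revcomp(substr(full, nchar(full) - read_len + 1L, nchar(full)))
    r1 <- rep(r1, each = reads_per_barcode)
    r2 <- rep(r2, each = reads_per_barcode)
    r1 <- .add_read_errors(r1, error_rate)
    r2 <- .add_read_errors(r2, error_rate)
    ids <- sprintf("pair%08d", seq_along(r1))
    q1 <- strrep(qual_char, nchar(r1))
    q2 <- strrep(qual_char, nchar(r2))
    list(read1 = data.frame(id = ids, seq = r1, qual = q1,
                            stringsAsFactors = FALSE),
         read2 = data.frame(id = ids, seq = r2, qual = q2,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate single-end tag reads for one sample
#'
#' Each tag read is the 20-bp barcode, the constant region, and a fixed
#' downstream filler; read multiplicities equal the sample's barcode count
#' column (zero-count barcodes emit no reads).
#'
#' @param library from [simulate_library()].
#' @param counts barcode-level count matrix (from [simulate_counts()]).
#' @param sample_id column of `counts` to emit.
#' @param error_rate per-base substitution rate (in [0, 0.2]).
#' @param read_len total read length.
#' @param constant_ref constant-region sequence.
#' @param qual_char quality character applied to every base.
#' @return data.frame(id, seq, qual).
#' @export
simulate_tag_reads <- function(library, counts, sample_id, error_rate = 0,
                               read_len = 100L,
                               constant_ref = CONSTANT_REGION,
                               qual_char = "I") {
  if (error_rate < 0 || error_rate > 0.2)
    stop("error_rate must be in [0, 0.2]")
  config <- library$config
  with_seed(child_seed(config$seed, paste0("tag_", sample_id)), {
    bc <- rownames(counts)
    ct <- counts[, sample_id]
    filler_len <- read_len - BARCODE_LEN - nchar(constant_ref)
    if (filler_len < 0) stop("read_len shorter than barcode + constant region")
    filler <- with_seed(child_seed(config$seed, "tag_filler"),
                        .random_dna_fast(1L, filler_len))
    tmpl <- paste0(bc, constant_ref, filler)
    seqs <- rep(tmpl, ct)
    seqs <- .add_read_errors(seqs, error_rate)
    data.frame(id = sprintf("%s_read%08d", sample_id, seq_along(seqs)),
               seq = seqs,
               qual = strrep(qual_char, nchar(seqs)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate ChIP-seq peak datasets and an eQTL table
#'
#' One "enriched" peak dataset covers `enriched_frac` of the planted allelic
#' variants but only `background_frac` of the others; `n_background` extra
#' datasets cover all variants uniformly at `background_frac`. The eQTL
#' table carries one gene per allelic variant with the effect sign matching
#' the planted allelic direction with probability `sign_consistency`, plus
#' uniform-noise rows for the other variants.
#'
#' @param library from [simulate_library()].
#' @param enriched_frac coverage of allelic variants by the enriched set.
#' @param background_frac uniform coverage fraction.
#' @param n_background number of background datasets.
#' @param sign_consistency probability an allelic variant's eQTL beta sign
#'   matches its planted direction.
#' @param peak_halfwidth half-width of each peak around the variant.
#' @param tissue tissue label written on every row.
#' @return list(peaks = named list of BED-style data.frames, eqtl =
#'   data.frame(variant_id, gene, effect_allele, beta, p, tissue_label)).
#' @export
simulate_peaks_eqtls <- function(library, enriched_frac = 0.8,
                                 background_frac = 0.1, n_background = 3L,
                                 sign_consistency = 1, peak_halfwidth = 50L,
                                 tissue = "LCL") {
  if (enriched_frac < 0 || enriched_frac > 1 ||
      background_frac < 0 || background_frac > 1 ||
      sign_consistency < 0 || sign_consistency > 1)
    stop("fractions must be in [0, 1]")
  config <- library$config
  variants <- library$variants
  tv <- library$truth$variant
  with_seed(child_seed(config$seed, "peaks_eqtls"), {
    allelic <- tv$allelic[match(variants$variant_id, tv$variant_id)]
    mk_peaks <- function(cover) {
      v <- variants[cover, , drop = FALSE]
      if (nrow(v) == 0L)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0)))
      data.frame(chrom = v$chrom,
                 start = v$pos - 1L - peak_halfwidth,
                 end = v$pos + peak_halfwidth,
                 name = paste0("peak_", v$variant_id),
                 stringsAsFactors = FALSE)
    }
    cover_enr <- ifelse(allelic, runif(nrow(variants)) < enriched_frac,
                        runif(nrow(variants)) < background_frac)
    peaks <- list(enriched = mk_peaks(cover_enr))
    for (k in seq_len(n_background)) {
      peaks[[sprintf("background_%d", k)]] <-
        mk_peaks(runif(nrow(variants)) < background_frac)
    }

    # eQTL rows: one informative row per allelic variant, noise for the rest
    al <- tv[tv$allelic, , drop = FALSE]
    sgn <- sign(al$log2_allelic)
    match_sign <- runif(nrow(al)) < sign_consistency
    beta <- abs(rnorm(nrow(al), 0.5, 0.1)) * ifelse(match_sign, sgn, -sgn)
    eq_allelic <- data.frame(
      variant_id = al$variant_id,
      gene = paste0("GENE_", al$variant_id),
      effect_allele = al$nonref_allele,
      beta = beta,
      p = runif(nrow(al), 0, 0.04),
      tissue_label = tissue,
      stringsAsFactors = FALSE)
    other <- tv[!tv$allelic, , drop = FALSE]
    eq_noise <- data.frame(
      variant_id = other$variant_id,
      gene = paste0("GENE_", other$variant_id),
      effect_allele = other$nonref_allele,
      beta = rnorm(nrow(other), 0, 0.3),
      p = runif(nrow(other)),
      tissue_label = tissue,
      stringsAsFactors = FALSE)
    list(peaks = peaks, eqtl = rbind(eq_allelic, eq_noise))
  })
}

#' Simple synthetic gene sets over a gene universe
#'
#' Builds `n_sets` random gene sets plus one set concentrated on the given
#' target genes, for exercising over-representation analysis.
#'
#' @param universe gene universe.
#' @param target genes to concentrate in the "target_set".
#' @param n_sets number of random sets.
#' @param set_size genes per random set.
#' @param seed RNG seed.
#' @return named list of gene vectors.
#' @export
simulate_gene_sets <- function(universe, target = character(0), n_sets = 10L,
                               set_size = 50L, seed = 1L) {
  with_seed(child_seed(seed, "gene_sets"), {
    sets <- lapply(seq_len(n_sets), function(k)
      sample(universe, min(set_size, length(universe))))
    names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
    if (length(target))
      sets$target_set <- unique(c(target,
        sample(universe, min(set_size, length(universe)))))
    sets
  })
}
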