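test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_variants = 15, n_loci = 5, barcodes_per_oligo_median = 6,
                    depth_per_sample = 5e3, n_cell_lines = 1, seed = 1)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$designs, b$designs)
  expect_identical(a$barcode_map, b$barcode_map)
  expect_identical(a$truth, b$truth)
  ca <- simulate_counts(a, cfg); cb <- simulate_counts(b, cfg)
  expect_identical(ca$counts, cb$counts)
  ra <- simulate_association_reads(a, 2L); rb <- simulate_association_reads(b, 2L)
  expect_identical(ra, rb)
  pa <- simulate_peaks_eqtls(a); pb <- simulate_peaks_eqtls(b)
  expect_identical(pa, pb)
  # a different seed changes the library
  cfg2 <- sim_config(n_variants = 15, n_loci = 5, barcodes_per_oligo_median = 6,
                     depth_per_sample = 5e3, n_cell_lines = 1, seed = 2)
  expect_false(identical(simulate_library(cfg2)$barcode_map, a$barcode_map))
})

test_that("library structure matches the configured study shape", {
  cfg <- sim_config(n_variants = 200, n_loci = 20, seed = 3)
  lib <- simulate_library(cfg)
  # every variant has >= 2 alleles; each (variant, allele) two orientations
  n_alleles <- lengths(strsplit(lib$variants$alt_alleles, ",")) + 1L
  expect_true(all(n_alleles >= 2))
  expect_equal(nrow(lib$designs), sum(n_alleles) * 2L)
  # barcodes are unique 20-mers over ACGT
  expect_false(anyDuplicated(lib$barcode_map$barcode) > 0)
  expect_true(all(nchar(lib$barcode_map$barcode) == 20L))
  expect_false(any(grepl("[^ACGT]", lib$barcode_map$barcode)))
  # every oligo appears exactly once in the truth table
  expect_equal(sort(lib$truth$oligo$oligo_id), sort(lib$designs$oligo_id))
  expect_false(anyDuplicated(lib$truth$oligo$oligo_id) > 0)
  # barcode-count median lands near the configured 239 (>= 1000 oligos)
  st <- map_stats(lib$barcode_map, lib$designs$oligo_id)
  expect_gte(nrow(st$per_oligo), 1000L)
  expect_gte(st$median_observed, 200)
  expect_lte(st$median_observed, 280)
})

test_that("alleles per variant hit the configured mean of 2.7", {
  set.seed(61)
  k <- sample_allele_counts(10000, 2.7)
  expect_true(all(k >= 2L & k <= 4L))
  expect_gte(mean(k), 2.6)
  expect_lte(mean(k), 2.8)
  expect_equal(sample_allele_counts(50, 2), rep(2L, 50))
})

test_that("null counts are centered and depth is conserved", {
  cfg <- sim_config(n_variants = 1900, n_loci = 50, depth_per_sample = 2e6,
                    frac_enhancer = 0, frac_silencer = 0, n_cell_lines = 1,
                    seed = 17)
  lib <- simulate_library(cfg)
  sim <- simulate_counts(lib, cfg, level = "oligo")
  expect_gte(nrow(sim$counts), 10000L)
  # column sums conserve the configured depth within NB sampling error (3 sd)
  mu <- cfg$depth_per_sample
  tol <- 3 * sqrt(sum((sim$counts[, 1] + cfg$nb_dispersion *
                         as.numeric(sim$counts[, 1])^2)))
  expect_true(all(abs(colSums(sim$counts) - mu) < tol))
  # mean per-oligo log2(RNA/plasmid) after size-factor normalization ~ 0
  sf <- size_factors(sim$counts)
  q <- sweep(sim$counts, 2, sf, "/")
  cond <- sim$samples$role == "rna"
  ratio <- log2(rowMeans(q[, cond]) + 0.5) - log2(rowMeans(q[, !cond]) + 0.5)
  expect_lt(abs(mean(ratio)), 0.05)
})

test_that("planted fold changes and allelic ratios are visible in the counts", {
  cfg <- sim_config(n_variants = 800, n_loci = 40, depth_per_sample = 4e6,
                    frac_enhancer = 0.15, frac_silencer = 0,
                    frac_allelic_given_regulatory = 0.5,
                    effect_fc_range_enh = c(2, 2),
                    allelic_ratio_range = c(1.5, 1.5),
                    n_cell_lines = 1, seed = 19)
  lib <- simulate_library(cfg)
  sim <- simulate_counts(lib, cfg, level = "oligo")
  sf <- size_factors(sim$counts)
  q <- sweep(sim$counts, 2, sf, "/")
  cond <- sim$samples$role == "rna"
  ratio <- rowMeans(q[, cond]) / rowMeans(q[, !cond])
  to <- lib$truth$oligo[match(rownames(sim$counts), lib$truth$oligo$oligo_id), ]
  # enhancer oligos carrying no allelic modifier: mean observed ratio near 2,
  # relative to the neutral baseline
  tv <- lib$truth$variant
  base <- mean(ratio[to$class == "neutral"])
  pure_enh <- to$class == "enhancer" &
    (to$allele_role == "Ref" | !tv$allelic[match(to$variant_id, tv$variant_id)])
  obs_fc <- mean(ratio[pure_enh]) / base
  expect_gte(obs_fc, 1.8); expect_lte(obs_fc, 2.2)

  # allelic variants with an unflipped planted ratio of 1.5: observed NR/R
  al <- tv[tv$allelic & tv$allelic_ratio > 1, ]
  nr_units <- paste0(al$variant_id, "_Alt1_", al$nonref_allele, "_fwd")
  r_units <- paste0(al$variant_id, "_Ref_", al$ref_allele, "_fwd")
  obs_ratio <- mean(ratio[nr_units] / ratio[r_units])
  expect_gte(obs_ratio, 1.35); expect_lte(obs_ratio, 1.65)
})

test_that("read simulators respect counts, error bounds and the retention rate", {
  cfg <- sim_config(n_variants = 10, n_loci = 5, barcodes_per_oligo_median = 6,
                    depth_per_sample = 2e4, n_cell_lines = 1, seed = 23)
  lib <- simulate_library(cfg)
  sim <- simulate_counts(lib, cfg)
  # zero-count barcodes emit zero reads; multiplicities equal the counts
  reads <- simulate_tag_reads(lib, sim$counts, "rna_CL1_1", error_rate = 0)
  expect_equal(nrow(reads), sum(sim$counts[, "rna_CL1_1"]))
  tab <- table(substr(reads$seq, 1, 20))
  nz <- sim$counts[sim$counts[, "rna_CL1_1"] > 0, "rna_CL1_1"]
  expect_equal(sort(as.integer(tab)), sort(unname(nz)))
  expect_error(simulate_tag_reads(lib, sim$counts, "rna_CL1_1", error_rate = 0.5),
               "\\[0, 0.2\\]")
  expect_error(simulate_association_reads(lib, error_rate = 0.3), "\\[0, 0.2\\]")

  # at 1% per-base error, >= 95% of tag reads pass the Levenshtein filter
  # (binomial on a 30-bp window: P(dist <= 4) ~ 1, junction ~ 0.99^2)
  reads_err <- simulate_tag_reads(lib, sim$counts, "plasmid_1", error_rate = 0.01)
  fl <- filter_tag_reads(reads_err)
  expect_gte(fl$n_accepted / nrow(reads_err), 0.95)
})

test_that("peak and eQTL simulation plants the requested coverage structure", {
  cfg <- sim_config(n_variants = 400, n_loci = 20,
                    barcodes_per_oligo_median = 5, depth_per_sample = 1e4,
                    frac_enhancer = 0.3, frac_silencer = 0.2,
                    frac_allelic_given_regulatory = 0.6, seed = 29)
  lib <- simulate_library(cfg)
  pe <- simulate_peaks_eqtls(lib, enriched_frac = 0.8, background_frac = 0.1)
  tv <- lib$truth$variant
  al_ids <- tv$variant_id[tv$allelic]
  ind <- suppressWarnings(overlap_indicator(lib$variants, pe$peaks$enriched))
  cov_al <- mean(ind[al_ids])
  cov_other <- mean(ind[setdiff(tv$variant_id, al_ids)])
  expect_gt(cov_al, 0.6)
  expect_lt(cov_other, 0.2)
  bg <- suppressWarnings(overlap_indicator(lib$variants, pe$peaks$background_1))
  expect_lt(mean(bg), 0.2)
  expect_error(simulate_peaks_eqtls(lib, enriched_frac = 1.2), "\\[0, 1\\]")
  # every allelic variant has an informative eQTL row
  expect_true(all(al_ids %in% pe$eqtl$variant_id))
})
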