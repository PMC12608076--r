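test_that("allele activity is the plasmid-normalized log2 ratio per replicate", {
  cond <- c(FALSE, FALSE, TRUE, TRUE)
  # RNA equal to the normalized plasmid mean: activity 0 (any pseudocount)
  m <- matrix(c(100, 100, 100, 100), nrow = 1,
              dimnames = list("u1", c("p1", "p2", "r1", "r2")))
  act <- allele_activity(m, cond, sf = rep(1, 4))
  expect_equal(unname(act["u1", ]), c(0, 0))

  # RNA at twice the plasmid mean: activity -> 1 as the pseudocount vanishes
  m2 <- matrix(c(100, 100, 200, 200), nrow = 1,
               dimnames = list("u1", c("p1", "p2", "r1", "r2")))
  act2 <- allele_activity(m2, cond, sf = rep(1, 4), pseudocount = 1e-9)
  expect_equal(unname(act2["u1", ]), c(1, 1), tolerance = 1e-6)

  # pseudocount keeps a zero RNA replicate finite
  m3 <- matrix(c(100, 100, 0, 200), nrow = 1,
               dimnames = list("u1", c("p1", "p2", "r1", "r2")))
  act3 <- allele_activity(m3, cond, sf = rep(1, 4))
  expect_true(all(is.finite(act3)))
  expect_error(allele_activity(m3, rep(TRUE, 4)), "plasmid")
})

test_that("allelic t-test matches the pooled-variance formula", {
  ref <- c(0.10, 0.20, 0.15)
  nonref <- c(0.60, 0.70, 0.65)
  got <- allelic_test(ref, nonref)
  # independent check against base R's Student's t-test
  tt <- t.test(nonref, ref, var.equal = TRUE)
  expect_equal(got$p, tt$p.value)
  expect_equal(got$t, unname(tt$statistic))
  expect_equal(got$log2_ratio, mean(nonref) - mean(ref))
  # and against the explicit textbook formula
  sp2 <- (2 * var(ref) + 2 * var(nonref)) / 4
  t_manual <- (mean(nonref) - mean(ref)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_manual)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 4))

  # identical vectors: ratio 0, p = 1 (including the zero-variance case)
  same <- allelic_test(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(same$log2_ratio, 0)
  expect_equal(same$p, 1)

  # swapping labels negates the ratio and preserves p
  sw <- allelic_test(nonref, ref)
  expect_equal(sw$log2_ratio, -got$log2_ratio)
  expect_equal(sw$p, got$p)
  expect_error(allelic_test(0.5, c(0.1, 0.2)), ">= 2 replicates")
})

test_that("allelic classification applies the 20% rule and variant class labels", {
  th <- default_thresholds()
  expect_equal(classify_allelic(log2(1.25), 0.01, "enhancer", th),
               "allelic_enhancer")
  expect_equal(classify_allelic(log2(1.10), 0.001, "enhancer", th),
               "not_allelic")
  expect_equal(classify_allelic(log2(0.80), 0.03, "silencer", th),
               "allelic_silencer")
  # exactly 20%: |log2 1.2| >= log2 1.2 holds (threshold is inclusive)
  expect_equal(classify_allelic(log2(1.2), 0.01, "enhancer", th),
               "allelic_enhancer")
  expect_error(classify_allelic(0.5, 0.01, "inactive", th),
               "enhancer or silencer")
})

test_that("multiallelic variants expand into one pair per nonreference allele", {
  expect_equal(nrow(multiallelic_expand(c("ref", "a1", "a2"))), 2L)
  expect_equal(nrow(multiallelic_expand(c("ref", "a1"))), 1L)
  p <- multiallelic_expand(c("r", "x", "y", "z"))
  expect_equal(p$ref, rep("r", 3))
  expect_equal(p$nonref, c("x", "y", "z"))
  expect_error(multiallelic_expand("r"), ">= 2 alleles")
})

test_that("allelic calls reference only regulatory variants and recover planted effects", {
  cfg <- sim_config(n_variants = 150, n_loci = 15,
                    barcodes_per_oligo_median = 60,
                    depth_per_sample = 2e6, n_cell_lines = 1,
                    frac_enhancer = 0.25, frac_silencer = 0.25,
                    frac_allelic_given_regulatory = 0.5,
                    allelic_ratio_range = c(1.5, 1.5), seed = 11)
  lib <- simulate_library(cfg)
  sim <- simulate_counts(lib, cfg)
  agg <- aggregate_to_oligo(sim$counts, lib$barcode_map, lib$designs$oligo_id)
  th <- default_thresholds()
  nbc <- plasmid_barcode_count(sim$counts, lib$barcode_map, sim$samples)
  act <- call_activity(agg$counts, sim$samples, lib$designs, "CL1",
                       n_plasmid_barcodes = nbc, thresholds = th)
  roll <- rollup_variants(act)
  al <- call_allelic(agg$counts, sim$samples, lib$designs, act,
                     roll$variant_classes, roll$contradictory, "CL1",
                     thresholds = th)
  # referential integrity: every allelic row's variant is regulatory
  reg <- roll$variant_classes[roll$variant_classes$enhancer |
                                roll$variant_classes$silencer, ]
  expect_true(all(al$variant_id %in% reg$variant_id))

  # planted allelic variants are substantially recovered at this depth
  tv <- lib$truth$variant
  planted <- tv$variant_id[tv$allelic & tv$variant_id %in% reg$variant_id]
  called <- unique(al$variant_id[al$allelic_class != "not_allelic"])
  expect_gte(mean(planted %in% called), 0.8)
  # and the estimated ratio magnitude tracks the planted 1.5
  hit <- al[al$variant_id %in% planted &
              al$nonref_allele ==
                tv$nonref_allele[match(al$variant_id, tv$variant_id)], ]
  planted_l2 <- tv$log2_allelic[match(hit$variant_id, tv$variant_id)]
  expect_lt(mean(abs(hit$log2_ratio - planted_l2)), 0.25)
})
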