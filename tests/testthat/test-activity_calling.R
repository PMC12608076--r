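test_that("plasmid barcode filter applies the >= 30 rule", {
  nbc <- c(a = 30L, b = 29L, c = 0L, d = 100L)
  expect_equal(filter_oligos(nbc), c("a", "d"))
})

test_that("size factors follow median-of-ratios arithmetic", {
  set.seed(41)
  base <- rnbinom(500, mu = 100, size = 10) + 1L
  m <- cbind(s1 = base, s2 = base)
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = base, s2 = 2L * base)
  sf <- size_factors(m2)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)

  # multiplying one sample by c multiplies its factor by c
  m3 <- cbind(s1 = base, s2 = base, s3 = 3L * base)
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3["s3"] / sf3["s1"]), 3)

  expect_error(size_factors(matrix(0L, 3, 2)), "pseudocount")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  set.seed(42)
  cond <- rep(c(FALSE, TRUE), each = 5)
  mus <- runif(2000, 50, 500)
  pois <- t(vapply(mus, function(m) rpois(10, m), numeric(10)))
  dp <- estimate_dispersion(pois, rep(1, 10), cond)
  expect_lte(median(dp), 0.01)

  nb <- t(vapply(mus, function(m) rnbinom(10, mu = m, size = 10), numeric(10)))
  dn <- estimate_dispersion(nb, rep(1, 10), cond)
  trend <- attr(dn, "trend")
  expect_gte(median(trend), 0.05)
  expect_lte(median(trend), 0.2)
  expect_gte(median(dn), 0.05)
  expect_lte(median(dn), 0.2)

  # constant counts: no variance anywhere, everything at the floor
  const <- matrix(7L, nrow = 50, ncol = 10)
  expect_true(all(estimate_dispersion(const, rep(1, 10), cond) <= 1e-8))
  expect_error(estimate_dispersion(pois[, c(1, 6)], rep(1, 2), c(FALSE, TRUE)),
               ">= 2 replicates")
})

test_that("NB Wald test recovers planted fold changes and is normalization-invariant", {
  set.seed(43)
  cond <- rep(c(FALSE, TRUE), each = 5)
  n <- 800
  mu0 <- runif(n, 500, 3000)
  # balanced planted effects so median-of-ratios normalization is unbiased
  fc <- rep(1, n); fc[1:100] <- 2; fc[101:200] <- 0.5
  y <- sapply(seq_len(10), function(j)
    rnbinom(n, mu = mu0 * (if (cond[j]) fc else rep(1, n)), size = 1 / 0.02))
  rownames(y) <- paste0("o", seq_len(n))
  res <- test_activity(y, cond)
  expect_lt(mean(abs(res$log2fc[1:100] - 1)), 0.15)
  expect_gt(mean(res$log2fc[1:100]), 0.9)
  expect_lt(mean(res$log2fc[1:100]), 1.1)
  expect_lt(mean(abs(res$log2fc[101:200] + 1)), 0.15)
  expect_lt(abs(mean(res$log2fc[201:n])), 0.05)

  # doubling all RNA counts and their size factors leaves log2fc unchanged
  sf <- size_factors(y)
  disp <- estimate_dispersion(y, sf, cond)
  base <- test_activity(y, cond, sf = sf, dispersion = disp)
  y2 <- y; y2[, cond] <- 2L * y2[, cond]
  sf2 <- sf; sf2[cond] <- 2 * sf2[cond]
  doubled <- test_activity(y2, cond, sf = sf2, dispersion = disp)
  expect_equal(doubled$log2fc, base$log2fc, tolerance = 1e-4)

  # all-zero RNA row gets the -Inf sentinel and a flag
  yz <- y[1:5, ]
  yz[3, cond] <- 0L
  rz <- test_activity(yz, cond, sf = sf, dispersion = disp[1:5])
  expect_true(rz$flagged[3])
  expect_equal(rz$log2fc[3], -Inf)
  expect_error(test_activity(y, rep(TRUE, 10)), "plasmid and RNA")
})

test_that("type-I error of the NB test is controlled near nominal", {
  set.seed(44)
  cond <- rep(c(FALSE, TRUE), each = 5)
  n <- 3000
  mu0 <- runif(n, 100, 1000)
  y <- sapply(seq_len(10), function(j) rnbinom(n, mu = mu0, size = 1 / 0.05))
  rownames(y) <- paste0("o", seq_len(n))
  res <- test_activity(y, cond)
  # null simulation: p >= 0.05 for at least 94% of oligos
  expect_gte(mean(res$p >= 0.05), 0.94)
})

test_that("fold-change estimates agree with DESeq2 on the same data", {
  skip_if_not_installed("DESeq2")
  set.seed(45)
  cond <- rep(c(FALSE, TRUE), each = 5)
  n <- 300
  mu0 <- runif(n, 200, 2000)
  fc <- c(rep(2, 60), rep(0.5, 60), rep(1, n - 120))
  y <- sapply(seq_len(10), function(j)
    rnbinom(n, mu = mu0 * (if (cond[j]) fc else rep(1, n)), size = 1 / 0.05))
  rownames(y) <- paste0("o", seq_len(n))
  mine <- test_activity(y, cond)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = y,
    colData = data.frame(condition = factor(ifelse(cond, "rna", "plasmid"),
                                            levels = c("plasmid", "rna"))),
    design = ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- DESeq2::results(dds)
  keep <- is.finite(mine$log2fc) & !is.na(dres$log2FoldChange)
  expect_gt(cor(mine$log2fc[keep], dres$log2FoldChange[keep]), 0.98)
  expect_lt(mean(abs(mine$log2fc[keep] - dres$log2FoldChange[keep])), 0.1)
})

test_that("BH adjustment matches hand examples and validates input", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(46)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("allele classification applies the FDR and 1.2-fold rules", {
  th <- default_thresholds()
  expect_equal(classify_allele(log2(1.25), 0.01, th), "enhancer")
  expect_equal(classify_allele(log2(1.5), 0.2, th), "inactive")
  expect_equal(classify_allele(log2(0.80), 0.04, th), "silencer")
  expect_equal(classify_allele(log2(1.19), 0.001, th), "inactive")
  # enhancer and silencer are mutually exclusive by construction
  cls <- classify_allele(c(-1, 0, 1), c(0.01, 0.01, 0.01), th)
  expect_equal(cls, c("silencer", "inactive", "enhancer"))
})

test_that("variant rollup applies any-allele rule and cross-line contradictions", {
  act <- data.frame(
    unit_id = c("v1_Ref_A", "v1_Alt1_G", "v2_Ref_C", "v2_Alt1_T",
                "v2_Ref_C", "v2_Alt1_T", "v3_Ref_A", "v3_Ref_A"),
    variant_id = c("v1", "v1", "v2", "v2", "v2", "v2", "v3", "v3"),
    allele = c("A", "G", "C", "T", "C", "T", "A", "A"),
    cell_line = c("CL1", "CL1", "CL1", "CL1", "CL1", "CL1", "CL1", "CL2"),
    activity_class = c("enhancer", "inactive", "enhancer", "silencer",
                       "enhancer", "silencer", "enhancer", "silencer"),
    stringsAsFactors = FALSE)
  # v2 rows duplicated within CL1 are harmless for the any-allele rule
  roll <- rollup_variants(act)
  vc <- roll$variant_classes
  expect_true(vc$enhancer[vc$variant_id == "v1" & vc$cell_line == "CL1"])
  # enhancer and silencer via different alleles in ONE cell line: both lists,
  # not contradictory
  expect_true(vc$enhancer[vc$variant_id == "v2" & vc$cell_line == "CL1"])
  expect_true(vc$silencer[vc$variant_id == "v2" & vc$cell_line == "CL1"])
  expect_false("v2" %in% roll$contradictory$variant_id)
  # same allele enhancer in CL1 and silencer in CL2: contradictory
  expect_equal(roll$contradictory$variant_id, "v3")
  expect_equal(roll$contradictory$allele, "A")
})

test_that("activity calls are invariant to sample order and oligo relabeling", {
  cfg <- tiny_config()
  lib <- simulate_library(cfg)
  sim <- simulate_counts(lib, cfg)
  agg <- aggregate_to_oligo(sim$counts, lib$barcode_map, lib$designs$oligo_id)
  th <- default_thresholds(min_plasmid_barcodes = 10)
  a1 <- call_activity(agg$counts, sim$samples, lib$designs, "CL1",
                      thresholds = th)
  perm <- sample(ncol(agg$counts))
  a2 <- call_activity(agg$counts[, perm], sim$samples, lib$designs, "CL1",
                      thresholds = th)
  a2 <- a2[match(a1$unit_id, a2$unit_id), ]
  expect_equal(a1$log2fc, a2$log2fc, tolerance = 1e-10)
  expect_equal(a1$activity_class, a2$activity_class)
})
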