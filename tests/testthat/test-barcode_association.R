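test_that("quality trimming removes low-quality ends and short reads", {
  # all bases at/above threshold: unchanged
  r <- data.frame(id = "a", seq = strrep("ACGT", 25),
                  qual = qs(rep(30, 100)), stringsAsFactors = FALSE)
  tr <- quality_trim(r, 25, 25, 80)
  expect_equal(tr$reads$seq, r$seq)
  expect_equal(tr$n_discarded, 0L)

  # exactly the 5 leading Q20 bases are removed
  r2 <- data.frame(id = "b", seq = strrep("A", 100),
                   qual = qs(c(rep(20, 5), rep(30, 95))),
                   stringsAsFactors = FALSE)
  tr2 <- quality_trim(r2, 25, 25, 80)
  expect_equal(nchar(tr2$reads$seq), 95L)

  # post-trim length 79 < MINLEN 80: discarded
  r3 <- data.frame(id = "c", seq = strrep("A", 100),
                   qual = qs(c(rep(20, 21), rep(30, 79))),
                   stringsAsFactors = FALSE)
  expect_equal(quality_trim(r3, 25, 25, 80)$n_discarded, 1L)
  expect_equal(nrow(quality_trim(r3, 25, 25, 80)$reads), 0L)

  # trailing trimming is symmetric
  r4 <- data.frame(id = "d", seq = strrep("A", 100),
                   qual = qs(c(rep(30, 90), rep(10, 10))),
                   stringsAsFactors = FALSE)
  expect_equal(nchar(quality_trim(r4, 25, 25, 80)$reads$seq), 90L)

  # malformed record errors with its index
  bad <- data.frame(id = "e", seq = "ACGT", qual = "III",
                    stringsAsFactors = FALSE)
  expect_error(quality_trim(bad), "record 1")
})

test_that("read 1 splits into a 20-bp barcode and the oligo region", {
  r <- data.frame(id = c("a", "b", "c"),
                  seq = c(strrep("A", 100), strrep("C", 20),
                          paste0(strrep("G", 10), "N", strrep("G", 9),
                                 strrep("T", 80))),
                  qual = c(qs(rep(30, 100)), qs(rep(30, 20)),
                           qs(rep(30, 100))),
                  stringsAsFactors = FALSE)
  sp <- split_read1(r)
  expect_equal(sp$barcode, strrep("A", 20))
  expect_equal(nchar(sp$oligo_region), 80L)
  expect_equal(sp$n_short, 1L)       # the 20-bp read
  expect_equal(sp$n_barcode_n, 1L)   # N inside the barcode
})

test_that("mate pairs match their oligo within the substitution budget", {
  set.seed(21)
  v <- data.frame(variant_id = c("rs1", "rs2"), chrom = "chrS1",
                  pos = c(1000L, 2000L), ref_allele = c("A", "C"),
                  alt_alleles = c("G", "T"), locus_id = "L001",
                  tier = "genome_wide", stringsAsFactors = FALSE)
  flanks <- list(rs1 = list(up = random_dna(1, 84), down = random_dna(1, 85)),
                 rs2 = list(up = random_dna(1, 84), down = random_dna(1, 85)))
  designs <- emit_oligos(v, flanks)$designs
  idx <- build_oligo_index(designs)
  full <- designs$full[designs$oligo_id == "rs1_Ref_A_fwd"]
  region <- substr(full, 1, 120)
  read2 <- revcomp(substr(full, 81, 200))
  expect_equal(match_oligo(region, read2, idx), "rs1_Ref_A_fwd")

  # three substitutions in one mate exceed the budget of 2
  bad <- region
  substr(bad, 5, 5) <- "N"; substr(bad, 15, 15) <- "N"; substr(bad, 25, 25) <- "N"
  expect_true(is.na(match_oligo(bad, read2, idx)))
  # two substitutions are within budget
  ok2 <- region
  substr(ok2, 5, 5) <- "N"; substr(ok2, 15, 15) <- "N"
  expect_equal(match_oligo(ok2, read2, idx), "rs1_Ref_A_fwd")

  # mates that avoid the allele base match two oligos equally: ambiguous.
  # rs1 alleles differ at full-sequence position 100 (fwd core offset 85);
  # a region covering 1..80 and a mate covering 121..200 never see it.
  region_short <- substr(full, 1, 80)
  read2_short <- revcomp(substr(full, 121, 200))
  expect_true(is.na(match_oligo(region_short, read2_short, idx)))
  # same outcome through the bulk path
  expect_true(is.na(match_oligo_bulk(region_short, read2_short, idx)))
  expect_equal(match_oligo_bulk(region, read2, idx), "rs1_Ref_A_fwd")
})

test_that("barcode map keeps modal oligo subject to support and purity", {
  asc <- data.frame(
    barcode = c(rep("B1", 10), rep("B2", 6), rep("B2", 4), "B3"),
    oligo_id = c(rep("A", 10), rep("A", 6), rep("B", 4), "A"),
    stringsAsFactors = FALSE)
  bm <- build_barcode_map(asc, min_support = 2L, min_purity = 0.9)
  expect_equal(bm$map$barcode, "B1")
  expect_equal(bm$map$purity, 1.0)
  expect_equal(bm$map$support_reads, 10L)
  expect_equal(bm$n_discarded_purity, 1L)  # B2 at purity 0.6
  expect_equal(bm$n_discarded_support, 1L) # B3 seen once
  expect_error(build_barcode_map(asc, min_purity = 0.4))
})

test_that("map statistics report per-oligo barcode counts and medians", {
  map <- data.frame(barcode = paste0("B", 1:6),
                    oligo_id = c("o1", "o2", "o2", "o3", "o3", "o3"),
                    stringsAsFactors = FALSE)
  st <- map_stats(map, design_oligo_ids = c("o1", "o2", "o3", "o4"))
  expect_equal(st$median_observed, 2)
  expect_equal(st$median_design, 1.5)  # zero-filled o4 enters the design median
  expect_error(map_stats(map[0, ]), "no associations")
})

test_that("error-free simulated reads recover the simulator's truth map exactly", {
  cfg <- sim_config(n_variants = 12, n_loci = 4, barcodes_per_oligo_median = 8,
                    depth_per_sample = 1e4, n_cell_lines = 1, seed = 5)
  lib <- simulate_library(cfg)
  rd <- simulate_association_reads(lib, reads_per_barcode = 3L, error_rate = 0)
  idx <- build_oligo_index(lib$designs)
  asc <- associate_barcodes(rd$read1, rd$read2, idx)
  expect_equal(asc$log$n_unmatched, 0L)
  bm <- build_barcode_map(asc$associations)
  got <- bm$map[order(bm$map$barcode), c("barcode", "oligo_id")]
  want <- lib$barcode_map[order(lib$barcode_map$barcode), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expect_true(all(bm$map$purity == 1))
  # support never exceeds the emitted read pairs
  expect_true(sum(bm$map$support_reads) <= nrow(rd$read1))
})
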