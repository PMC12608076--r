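# Gene annotation of allelic regulatory variants via eQTL records whose
# direction of effect matches the allelic MPRA effect, and gene-set
# over-representation on the resulting gene lists.

#' Direction match between an allelic result and an eQTL record
#'
#' Harmonizes the eQTL effect to the nonreference allele (the beta sign is
#' flipped when the effect allele is the reference allele) and returns TRUE
#' iff the harmonized beta has the same sign as the allelic log2 ratio.
#' Zero beta or zero ratio never match.
#'
#' @param log2_ratio allelic nonref-vs-ref log2 activity ratio.
#' @param ref_allele,nonref_allele the variant's tested alleles.
#' @param effect_allele,beta the eQTL record's effect allele and effect size.
#' @return logical.
#' @export
direction_match <- function(log2_ratio, ref_allele, nonref_allele,
                            effect_allele, beta) {
  n <- length(log2_ratio)
  harmonized <- numeric(n)
  is_nonref <- effect_allele == nonref_allele
  is_ref <- effect_allele == ref_allele
  if (any(!is_nonref & !is_ref))
    stop("allele mismatch: effect allele matches neither tested allele")
  harmonized[is_nonref] <- beta[is_nonref]
  harmonized[is_ref] <- -beta[is_ref]
  sign(harmonized) != 0 & sign(log2_ratio) != 0 &
    sign(harmonized) == sign(log2_ratio)
}

#' Annotate allelic variants with direction-matched eQTL genes
#'
#' Keeps (variant, gene) pairs whose eQTL record is nominally significant
#' (p below `eqtl_nominal_p`), measured in the requested tissue, and whose
#' direction of effect matches the allelic effect. Records whose effect
#' allele matches neither tested allele are dropped (tallied), not an error,
#' since public eQTL tables mix strands and builds.
#'
#' @param allelic allelic results (from [call_allelic()], rows with
#'   allelic_class != "not_allelic" are used).
#' @param eqtl data.frame(variant_id, gene, effect_allele, beta, p,
#'   tissue_label).
#' @param tissue exact tissue label to keep (e.g. "LCL").
#' @param thresholds from [default_thresholds()].
#' @return list(pairs = data.frame(variant_id, gene, cell_line,
#'   allelic_class, log2_ratio, beta_harmonized, eqtl_p), genes = named list
#'   of deduplicated gene vectors per allelic class, n_allele_mismatch).
#' @export
annotate_genes <- function(allelic, eqtl, tissue = "LCL",
                           thresholds = default_thresholds()) {
  hits <- allelic[allelic$allelic_class != "not_allelic", , drop = FALSE]
  eq <- eqtl[eqtl$tissue_label == tissue &
               eqtl$p < thresholds$eqtl_nominal_p, , drop = FALSE]
  j <- merge(hits, eq, by = "variant_id", suffixes = c("", ".eqtl"))
  n_mismatch <- 0L
  if (nrow(j)) {
    valid <- j$effect_allele == j$ref_allele |
      j$effect_allele == j$nonref_allele
    n_mismatch <- sum(!valid)
    j <- j[valid, , drop = FALSE]
  }
  if (nrow(j)) {
    harm <- ifelse(j$effect_allele == j$nonref_allele, j$beta, -j$beta)
    keep <- direction_match(j$log2_ratio, j$ref_allele, j$nonref_allele,
                            j$effect_allele, j$beta)
    j <- j[keep, , drop = FALSE]
    harm <- harm[keep]
  } else harm <- numeric(0)
  pairs <- data.frame(variant_id = j$variant_id, gene = j$gene,
                      cell_line = j$cell_line,
                      allelic_class = j$allelic_class,
                      log2_ratio = j$log2_ratio,
                      beta_harmonized = harm,
                      eqtl_p = j$p, stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs[, c("variant_id", "gene", "cell_line")]), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  genes <- lapply(split(pairs$gene, pairs$allelic_class), unique)
  list(pairs = pairs, genes = genes, n_allele_mismatch = n_mismatch)
}

#' Gene-set over-representation (one-sided Fisher's exact test)
#'
#' For each gene set, tests whether the gene list overlaps the set more than
#' expected from the background universe (2x2 table, alternative =
#' "greater"), BH-adjusts across sets, and flags sets with fewer than
#' `min_overlap` overlapping genes (below the display threshold).
#'
#' @param gene_list character vector of genes (subset of `background`).
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param background gene universe.
#' @param min_overlap display threshold on overlapping genes.
#' @return data.frame(gene_set, n_set, n_list, overlap, odds_ratio, p, padj,
#'   below_display_threshold), sorted by p.
#' @export
overrepresentation <- function(gene_list, gene_sets, background,
                               min_overlap = 5L) {
  if (length(background) == 0L) stop("empty background universe")
  background <- unique(background)
  gene_list <- unique(intersect(gene_list, background))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    a <- length(intersect(gene_list, set))
    b <- length(gene_list) - a
    c_ <- length(set) - a
    d <- length(background) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                      alternative = "greater")
    data.frame(gene_set = nm, n_set = length(set),
               n_list = length(gene_list), overlap = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out$below_display_threshold <- out$overlap < min_overlap
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
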