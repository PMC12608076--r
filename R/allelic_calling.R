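# Allelic calling: among variants already classed as regulatory, test
# whether the nonreference allele's activity differs from the reference
# allele's by comparing per-replicate log2 activity ratios (plasmid
# normalized) with Student's t-test and the 20% effect-size threshold.

#' Per-replicate allele activity
#'
#' Activity of a testing unit (one allele) in RNA replicate r is
#' `log2((count_r / sf_r + pc) / (mean over plasmid replicates of
#' count_p / sf_p + pc))`. The pseudocount keeps activities finite for
#' zero-count replicates.
#'
#' @param unit_counts count matrix (units x samples; plasmid replicates plus
#'   the RNA replicates of one cell line).
#' @param condition logical vector over columns (TRUE = RNA).
#' @param sf size factors (length = ncol); computed when NULL.
#' @param pseudocount added to normalized counts before the ratio.
#' @return matrix units x RNA replicates of log2 activities.
#' @export
allele_activity <- function(unit_counts, condition, sf = NULL,
                            pseudocount = 0.5) {
  condition <- as.logical(condition)
  if (sum(!condition) < 1L) stop("plasmid replicates required")
  if (is.null(sf)) sf <- size_factors(unit_counts)
  q <- sweep(unit_counts, 2L, sf, "/")
  pl_mean <- rowMeans(q[, !condition, drop = FALSE])
  act <- log2(sweep(q[, condition, drop = FALSE] + pseudocount,
                    1L, pl_mean + pseudocount, "/"))
  colnames(act) <- colnames(unit_counts)[condition]
  act
}

#' Student's t-test between allele activity vectors
#'
#' Two-sample pooled-variance t-test of the nonreference allele's
#' per-replicate activities against the reference allele's. The effect is
#' `log2_ratio = mean(nonref) - mean(ref)` (log2 nonreference/reference
#' activity ratio). Identical constant vectors give p = 1.
#'
#' @param ref_act,nonref_act numeric vectors of per-replicate activities
#'   (length >= 2 each).
#' @return list(log2_ratio, t, df, p).
#' @export
allelic_test <- function(ref_act, nonref_act) {
  n0 <- length(ref_act); n1 <- length(nonref_act)
  if (n0 < 2L || n1 < 2L) stop("need >= 2 replicates per allele")
  m0 <- mean(ref_act); m1 <- mean(nonref_act)
  delta <- m1 - m0
  sp2 <- ((n0 - 1) * var(ref_act) + (n1 - 1) * var(nonref_act)) /
    (n0 + n1 - 2)
  df <- n0 + n1 - 2
  if (sp2 <= 0) {
    # degenerate: zero within-group variance
    if (delta == 0) return(list(log2_ratio = 0, t = 0, df = df, p = 1))
    return(list(log2_ratio = delta, t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / sqrt(sp2 * (1 / n0 + 1 / n1))
  list(log2_ratio = delta, t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Expand a variant into (reference, nonreference) test pairs
#'
#' One test per nonreference allele against the reference allele.
#'
#' @param alleles character vector of the variant's alleles present in the
#'   retained units; the first must be the reference.
#' @return data.frame(ref, nonref), one row per pair.
#' @export
multiallelic_expand <- function(alleles) {
  if (length(alleles) < 2L) stop("need >= 2 alleles to form test pairs")
  data.frame(ref = alleles[1L], nonref = alleles[-1L],
             stringsAsFactors = FALSE)
}

#' Classify an allelic test result
#'
#' Allelic iff padj below `fdr_alpha` and |log2_ratio| at least
#' log2(`allelic_fc`); the label follows the variant's activity class
#' (allelic_enhancer for enhancer variants, allelic_silencer for silencer
#' variants).
#'
#' @param log2_ratio nonref-vs-ref log2 activity ratio.
#' @param padj BH-adjusted p-value.
#' @param variant_class "enhancer" or "silencer" (the variant's class in
#'   this cell line; inactive variants are an error — pre-filter).
#' @param thresholds from [default_thresholds()].
#' @return character: "allelic_enhancer", "allelic_silencer" or
#'   "not_allelic".
#' @export
classify_allelic <- function(log2_ratio, padj, variant_class,
                             thresholds = default_thresholds()) {
  if (any(!variant_class %in% c("enhancer", "silencer")))
    stop("allelic classification requires an enhancer or silencer variant")
  lt <- log2(thresholds$allelic_fc)
  sig <- !is.na(padj) & padj < thresholds$fdr_alpha & abs(log2_ratio) >= lt
  out <- rep("not_allelic", length(log2_ratio))
  out[sig] <- ifelse(variant_class[sig] == "enhancer",
                     "allelic_enhancer", "allelic_silencer")
  out
}

#' Call allelic regulatory variants in one cell line
#'
#' Driver: restricts to variants classed enhancer or silencer in this cell
#' line (minus contradictory variant+alleles) and, for every (reference,
#' nonreference) pair, compares the per-replicate log2 nonreference/reference
#' count ratios of the RNA replicates against the same ratios in the plasmid
#' controls with Student's t-test. Contrasting allele ratios between the two
#' replicate groups (rather than subtracting a shared estimated plasmid mean
#' from each allele's activities) keeps the test's variance estimate honest:
#' both groups are independent observations of the allelic ratio, so the
#' plasmid normalization noise enters the null distribution instead of being
#' hidden from it. The reported effect `log2_ratio = mean(RNA ratios) -
#' mean(plasmid ratios)` is the plasmid-normalized allelic activity ratio.
#' Tests are BH-adjusted across all pairs in the cell line and classified
#' with the effect-size threshold; a variant is allelic if any of its pairs
#' is.
#'
#' @param oligo_counts oligo-level count matrix (all samples).
#' @param samples sample sheet.
#' @param designs oligo design data.frame.
#' @param activity allele-level activity results for this cell line (from
#'   [call_activity()]).
#' @param variant_classes variant-level classes (from [rollup_variants()]).
#' @param contradictory data.frame(variant_id, allele) to exclude.
#' @param cell_line cell line to analyse.
#' @param thresholds from [default_thresholds()].
#' @param pseudocount for [allele_activity()].
#' @param pool_orientations must match the activity run.
#' @return data.frame: variant_id, cell_line, ref_allele, nonref_allele,
#'   variant_class, log2_ratio, t, p, padj, allelic_class.
#' @export
call_allelic <- function(oligo_counts, samples, designs, activity,
                         variant_classes, contradictory = NULL,
                         cell_line, thresholds = default_thresholds(),
                         pseudocount = 0.5, pool_orientations = TRUE) {
  vc <- variant_classes[variant_classes$cell_line == cell_line, , drop = FALSE]
  reg <- vc[vc$enhancer | vc$silencer, , drop = FALSE]
  if (nrow(reg) == 0L)
    return(data.frame(variant_id = character(0), cell_line = character(0),
                      ref_allele = character(0), nonref_allele = character(0),
                      variant_class = character(0), log2_ratio = numeric(0),
                      t = numeric(0), p = numeric(0), padj = numeric(0),
                      allelic_class = character(0), stringsAsFactors = FALSE))

  act <- activity[activity$cell_line == cell_line, , drop = FALSE]
  if (!is.null(contradictory) && nrow(contradictory)) {
    bad <- paste(act$variant_id, act$allele) %in%
      paste(contradictory$variant_id, contradictory$allele)
    act <- act[!bad, , drop = FALSE]
  }

  pl <- samples$sample_id[samples$role == "plasmid"]
  rna <- samples$sample_id[samples$role == "rna" &
                             samples$cell_line == cell_line]
  cols <- c(pl, rna)
  di <- match(rownames(oligo_counts), designs$oligo_id)
  unit <- if (pool_orientations)
    paste(designs$variant_id[di], designs$allele_role[di],
          designs$allele[di], sep = "_")
  else rownames(oligo_counts)
  umat <- rowsum(oligo_counts[, cols, drop = FALSE], group = unit)
  umat <- umat[rownames(umat) %in% act$unit_id, , drop = FALSE]
  condition <- colnames(umat) %in% rna
  sf <- size_factors(umat)
  q <- sweep(umat, 2L, sf, "/")

  rows <- list()
  for (v in reg$variant_id) {
    va <- act[act$variant_id == v, , drop = FALSE]
    # reference first, then alternates in design order
    va <- va[order(va$allele_role != "Ref", va$allele_role), , drop = FALSE]
    if (nrow(va) < 2L || va$allele_role[1L] != "Ref") next  # ref not retained
    pairs <- multiallelic_expand(va$unit_id)
    vclass <- if (reg$enhancer[reg$variant_id == v]) "enhancer" else "silencer"
    for (k in seq_len(nrow(pairs))) {
      lr <- log2((q[pairs$nonref[k], ] + pseudocount) /
                   (q[pairs$ref[k], ] + pseudocount))
      tst <- allelic_test(lr[!condition], lr[condition])
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = v, cell_line = cell_line,
        ref_allele = va$allele[va$unit_id == pairs$ref[k]],
        nonref_allele = va$allele[va$unit_id == pairs$nonref[k]],
        variant_class = vclass,
        log2_ratio = tst$log2_ratio, t = tst$t, p = tst$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(variant_id = character(0), cell_line = character(0),
                      ref_allele = character(0), nonref_allele = character(0),
                      variant_class = character(0), log2_ratio = numeric(0),
                      t = numeric(0), p = numeric(0), padj = numeric(0),
                      allelic_class = character(0), stringsAsFactors = FALSE))
  out$padj <- bh_adjust(out$p)
  out$allelic_class <- classify_allelic(out$log2_ratio, out$padj,
                                        out$variant_class, thresholds)
  rownames(out) <- NULL
  out
}

#' Variant-level allelic summary across cell lines
#'
#' A variant is allelic in a cell line if any of its test pairs is; the
#' cross-cell-line summary is the set union (not the sum).
#'
#' @param allelic rbind of [call_allelic()] results across cell lines.
#' @return list(per_cell_line = data.frame(cell_line, variant_id,
#'   allelic_class), union = data.frame(variant_id, allelic_enhancer,
#'   allelic_silencer, cell_lines)).
#' @export
summarize_allelic <- function(allelic) {
  hit <- allelic[allelic$allelic_class != "not_allelic", , drop = FALSE]
  per <- unique(hit[, c("cell_line", "variant_id", "allelic_class")])
  rownames(per) <- NULL
  if (nrow(hit) == 0L)
    return(list(per_cell_line = per,
                union = data.frame(variant_id = character(0),
                                   allelic_enhancer = logical(0),
                                   allelic_silencer = logical(0),
                                   cell_lines = character(0))))
  u <- split(per, per$variant_id)
  un <- data.frame(
    variant_id = names(u),
    allelic_enhancer = vapply(u, function(d)
      any(d$allelic_class == "allelic_enhancer"), logical(1)),
    allelic_silencer = vapply(u, function(d)
      any(d$allelic_class == "allelic_silencer"), logical(1)),
    cell_lines = vapply(u, function(d)
      paste(sort(unique(d$cell_line)), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_cell_line = per, union = un)
}
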