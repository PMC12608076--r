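# Enhancer/silencer calling: negative-binomial differential test of RNA
# replicates against plasmid controls, with median-of-ratios normalization,
# trend-shrunk method-of-moments dispersions and a Wald test, followed by
# BH correction, fold-change thresholds and variant-level rollup.

#' Default analysis thresholds
#'
#' @param min_plasmid_barcodes minimum unique barcodes across plasmid
#'   replicates for an oligo to be tested.
#' @param fdr_alpha BH-adjusted significance level.
#' @param activity_fc minimum fold change (either direction) for an
#'   enhancer/silencer call.
#' @param allelic_fc minimum between-allele fold change (the "20%" rule).
#' @param reli_iterations resampling iterations for peak-set enrichment.
#' @param eqtl_nominal_p nominal eQTL p-value cutoff for gene annotation.
#' @return named list of thresholds.
#' @export
default_thresholds <- function(min_plasmid_barcodes = 30L, fdr_alpha = 0.05,
                               activity_fc = 1.2, allelic_fc = 1.2,
                               reli_iterations = 2000L,
                               eqtl_nominal_p = 0.05) {
  stopifnot(min_plasmid_barcodes > 0, fdr_alpha > 0, fdr_alpha < 1,
            activity_fc > 0, allelic_fc > 0, reli_iterations > 0,
            eqtl_nominal_p > 0)
  list(min_plasmid_barcodes = as.integer(min_plasmid_barcodes),
       fdr_alpha = fdr_alpha, activity_fc = activity_fc,
       allelic_fc = allelic_fc, reli_iterations = as.integer(reli_iterations),
       eqtl_nominal_p = eqtl_nominal_p)
}

#' Unique plasmid barcodes per oligo
#'
#' Counts, per oligo, the unique barcodes observed (count > 0) in the plasmid
#' replicates — by default in their union, optionally requiring detection in
#' every plasmid replicate.
#'
#' @param bc_counts barcode-level count matrix (barcode rownames).
#' @param map barcode map (barcode, oligo_id).
#' @param samples sample sheet data.frame(sample_id, role, cell_line,
#'   replicate); plasmid columns are those with role == "plasmid".
#' @param mode `"union"` (default) or `"per_replicate"`.
#' @return named integer vector over oligo ids present in the map.
#' @export
plasmid_barcode_count <- function(bc_counts, map, samples,
                                  mode = c("union", "per_replicate")) {
  mode <- match.arg(mode)
  pl <- samples$sample_id[samples$role == "plasmid"]
  if (length(pl) == 0L) stop("no plasmid columns in sample sheet")
  sub <- bc_counts[, pl, drop = FALSE]
  seen <- if (mode == "union") rowSums(sub > 0L) > 0L else
    rowSums(sub > 0L) == length(pl)
  oligo <- map$oligo_id[match(rownames(bc_counts), map$barcode)]
  tab <- rowsum(seen + 0L, group = oligo)
  setNames(as.integer(tab), rownames(tab))
}

#' Filter oligos on plasmid barcode support
#'
#' Retains oligos with at least `min_plasmid_barcodes` unique barcodes in the
#' plasmid replicates.
#'
#' @param n_plasmid_barcodes named integer vector (see
#'   [plasmid_barcode_count()]).
#' @param thresholds from [default_thresholds()].
#' @return character vector of retained oligo ids.
#' @export
filter_oligos <- function(n_plasmid_barcodes, thresholds = default_thresholds()) {
  names(n_plasmid_barcodes)[n_plasmid_barcodes >=
                              thresholds$min_plasmid_barcodes]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over oligos with
#' all-positive counts, of the ratio of the sample's count to the oligo's
#' geometric mean across samples.
#'
#' @param mat count matrix (oligos x samples).
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(mat) {
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos))
    stop("no oligo has positive counts in all samples; ",
         "consider a pseudocount before normalization")
  lm_ <- log(mat[pos, , drop = FALSE])
  geo <- rowMeans(lm_)
  sf <- exp(apply(lm_ - geo, 2L, median))
  setNames(sf, colnames(mat))
}

#' Per-oligo NB dispersion with trend shrinkage
#'
#' Method-of-moments dispersion per oligo from normalized counts, pooled
#' across the two conditions, then shrunk toward a mean-dispersion trend
#' (dispersion ~ a0 + a1/mean) fitted across oligos. Floored at 1e-8.
#'
#' @param mat count matrix (oligos x samples).
#' @param sf size factors (length = ncol(mat)).
#' @param condition logical/0-1 vector over samples (TRUE = RNA).
#' @param prior_df weight of the trend in the shrinkage (in pseudo-degrees
#'   of freedom).
#' @return numeric vector of shrunk dispersions with attributes `raw`,
#'   `trend` and `base_mean`.
#' @export
estimate_dispersion <- function(mat, sf, condition, prior_df = 10) {
  condition <- as.logical(condition)
  n_by <- c(sum(!condition), sum(condition))
  if (any(n_by < 2L)) stop("need >= 2 replicates per condition")
  q <- sweep(mat, 2L, sf, "/")
  floor_ <- 1e-8

  mom <- function(sub, sfs) {
    m <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    xi <- mean(1 / sfs)
    phi <- (v - m * xi) / m^2
    phi[!is.finite(phi)] <- 0
    phi
  }
  phi0 <- mom(q[, !condition, drop = FALSE], sf[!condition])
  phi1 <- mom(q[, condition, drop = FALSE], sf[condition])
  w0 <- n_by[1L] - 1L; w1 <- n_by[2L] - 1L
  raw <- pmax((phi0 * w0 + phi1 * w1) / (w0 + w1), 0)
  base_mean <- rowMeans(q)

  usable <- raw > floor_ & base_mean > 0
  if (sum(usable) >= 10L) {
    fit <- try(lm(raw[usable] ~ I(1 / base_mean[usable])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      a <- pmax(coef(fit), 0)
      trend <- pmax(a[1L] + a[2L] / pmax(base_mean, 1e-8), floor_)
    } else trend <- rep(max(median(raw[usable]), floor_), nrow(mat))
  } else {
    trend <- rep(max(if (any(usable)) median(raw[usable]) else 0, floor_),
                 nrow(mat))
  }
  df_resid <- length(condition) - 2L
  shrunk <- pmax((raw * df_resid + trend * prior_df) / (df_resid + prior_df),
                 floor_)
  structure(setNames(shrunk, rownames(mat)),
            raw = raw, trend = trend, base_mean = base_mean)
}

# Vectorized IRLS for a per-oligo NB GLM with log link, known dispersion,
# design = intercept + condition, offset = log(size factor). Returns the
# Wald test on the condition coefficient for every row at once.
nb_wald <- function(mat, sf, condition, dispersion,
                    ref_dist = c("t", "normal"), max_iter = 50L, tol = 1e-8) {
  ref_dist <- match.arg(ref_dist)
  condition <- as.logical(condition)
  x <- as.numeric(condition)
  o <- log(sf)
  n <- nrow(mat); m <- ncol(mat)
  phi <- rep_len(as.numeric(dispersion), n)
  y <- mat

  q <- sweep(y, 2L, sf, "/")
  mu0 <- rowMeans(q[, !condition, drop = FALSE])
  mu1 <- rowMeans(q[, condition, drop = FALSE])
  zero0 <- mu0 == 0
  zero1 <- mu1 == 0
  flagged <- zero0 | zero1
  # boundary rows: refit with a half-count added so the GLM stays interior;
  # the fold change itself is reported as an infinite sentinel
  if (any(flagged)) y[flagged, ] <- y[flagged, , drop = FALSE] + 0.5
  qf <- sweep(y, 2L, sf, "/")
  b0 <- log(pmax(rowMeans(qf[, !condition, drop = FALSE]), 1e-8))
  b1 <- log(pmax(rowMeans(qf[, condition, drop = FALSE]), 1e-8)) - b0

  xm <- matrix(x, nrow = n, ncol = m, byrow = TRUE)
  om <- matrix(o, nrow = n, ncol = m, byrow = TRUE)
  A11 <- A12 <- det <- rep(1, n)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * xm + om
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + phi * mu)
    z <- eta - om + (y - mu) / mu
    wx <- w * xm
    A11 <- rowSums(w)
    A12 <- rowSums(wx)
    A22 <- A12  # x is binary
    s1 <- rowSums(w * z)
    s2 <- rowSums(wx * z)
    det <- A11 * A22 - A12^2
    ok <- is.finite(det) & det > 1e-12
    nb0 <- ifelse(ok, (A22 * s1 - A12 * s2) / det, b0)
    nb1 <- ifelse(ok, (A11 * s2 - A12 * s1) / det, b1)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    if (max(delta, na.rm = TRUE) < tol) break
  }
  se <- sqrt(pmax(A11 / pmax(det, 1e-300), 0))
  stat <- b1 / se
  p <- if (ref_dist == "t") 2 * pt(-abs(stat), df = m - 2L) else
    2 * pnorm(-abs(stat))
  log2fc <- b1 / log(2)
  log2fc[zero1 & !zero0] <- -Inf
  log2fc[zero0 & !zero1] <- Inf
  data.frame(base_mean = rowMeans(q), log2fc = log2fc, se = se / log(2),
             stat = stat, p = p, flagged = flagged,
             row.names = rownames(mat))
}

#' NB differential activity test of RNA replicates against plasmid controls
#'
#' Fits, per oligo, a negative-binomial GLM with a condition indicator
#' (plasmid vs RNA) and log size-factor offsets, and tests the condition
#' coefficient (Wald). The Wald statistic is referred to a t distribution
#' with n - 2 degrees of freedom to account for dispersion estimation.
#'
#' @param mat count matrix (retained oligos x samples) containing the
#'   plasmid replicates and the RNA replicates of one cell line.
#' @param condition logical vector over columns (TRUE = RNA).
#' @param sf size factors; computed by [size_factors()] when NULL.
#' @param dispersion per-oligo dispersions; computed by
#'   [estimate_dispersion()] when NULL.
#' @param ref_dist reference distribution for the Wald statistic.
#' @return data.frame(base_mean, log2fc, se, stat, p, flagged), rownames =
#'   oligo ids. `log2fc` is RNA vs plasmid (log2); all-zero RNA rows get a
#'   -Inf sentinel and `flagged = TRUE`.
#' @export
test_activity <- function(mat, condition, sf = NULL, dispersion = NULL,
                          ref_dist = c("t", "normal")) {
  condition <- as.logical(condition)
  if (!any(condition) || !any(!condition))
    stop("both plasmid and RNA columns are required")
  if (is.null(sf)) sf <- size_factors(mat)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(mat, sf, condition)
  nb_wald(mat, sf, condition, dispersion, ref_dist = match.arg(ref_dist))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; validates inputs.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify alleles as enhancer / silencer / inactive
#'
#' Enhancer: padj below `fdr_alpha` and fold change greater than
#' `activity_fc`; silencer: padj below `fdr_alpha` and fold change below
#' `1/activity_fc`; otherwise inactive.
#'
#' @param log2fc log2 fold change (RNA vs plasmid).
#' @param padj BH-adjusted p-values.
#' @param thresholds from [default_thresholds()].
#' @return character vector over {"enhancer", "silencer", "inactive"}.
#' @export
classify_allele <- function(log2fc, padj, thresholds = default_thresholds()) {
  lt <- log2(thresholds$activity_fc)
  out <- rep("inactive", length(log2fc))
  sig <- !is.na(padj) & padj < thresholds$fdr_alpha
  out[sig & log2fc > lt] <- "enhancer"
  out[sig & log2fc < -lt] <- "silencer"
  out
}

#' Call enhancer and silencer alleles in one cell line
#'
#' Driver for one cell line: pools forward/reverse-complement oligo counts
#' per (variant, allele) testing unit (orientations are technical
#' duplicates), applies the plasmid-barcode filter, normalizes, tests,
#' BH-adjusts across all retained units in the cell line, and classifies.
#'
#' @param oligo_counts oligo-level count matrix (all samples).
#' @param samples sample sheet (sample_id, role, cell_line, replicate).
#' @param designs oligo design data.frame (oligo_id, variant_id, allele).
#' @param cell_line cell line whose RNA replicates to test.
#' @param n_plasmid_barcodes per-oligo unique plasmid barcode counts (named;
#'   see [plasmid_barcode_count()]); NULL skips the filter (all oligos kept).
#' @param thresholds from [default_thresholds()].
#' @param pool_orientations pool fwd/rc counts per (variant, allele)
#'   (default) or test each oligo separately.
#' @return data.frame: unit_id, variant_id, allele, cell_line,
#'   n_plasmid_barcodes, base_mean, log2fc, se, p, padj, activity_class,
#'   flagged.
#' @export
call_activity <- function(oligo_counts, samples, designs, cell_line,
                          n_plasmid_barcodes = NULL,
                          thresholds = default_thresholds(),
                          pool_orientations = TRUE) {
  pl <- samples$sample_id[samples$role == "plasmid"]
  rna <- samples$sample_id[samples$role == "rna" &
                             samples$cell_line == cell_line]
  if (length(pl) == 0L) stop("no plasmid columns in sample sheet")
  if (length(rna) == 0L) stop("no RNA columns for cell line ", cell_line)
  cols <- c(pl, rna)
  mat <- oligo_counts[, cols, drop = FALSE]

  di <- match(rownames(mat), designs$oligo_id)
  if (anyNA(di)) stop("count rows not in design: ",
                      rownames(mat)[is.na(di)][1L])
  unit <- if (pool_orientations)
    paste(designs$variant_id[di], designs$allele_role[di],
          designs$allele[di], sep = "_")
  else rownames(mat)
  umat <- rowsum(mat, group = unit)
  ui <- match(rownames(umat), unit)
  meta <- data.frame(unit_id = rownames(umat),
                     variant_id = designs$variant_id[di][ui],
                     allele = designs$allele[di][ui],
                     allele_role = designs$allele_role[di][ui],
                     stringsAsFactors = FALSE)

  if (!is.null(n_plasmid_barcodes)) {
    per_oligo <- setNames(rep(0L, nrow(mat)), rownames(mat))
    hit <- intersect(names(n_plasmid_barcodes), rownames(mat))
    per_oligo[hit] <- n_plasmid_barcodes[hit]
    nbc <- rowsum(per_oligo, group = unit)[rownames(umat), 1L]
  } else {
    nbc <- setNames(rep(NA_integer_, nrow(umat)), rownames(umat))
  }
  keep <- if (is.null(n_plasmid_barcodes)) rep(TRUE, nrow(umat)) else
    nbc >= thresholds$min_plasmid_barcodes
  umat <- umat[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  nbc <- nbc[keep]
  if (nrow(umat) == 0L) stop("no units pass the plasmid barcode filter")

  condition <- colnames(umat) %in% rna
  res <- test_activity(umat, condition)
  padj <- bh_adjust(res$p)
  data.frame(meta,
             cell_line = cell_line,
             n_plasmid_barcodes = as.integer(nbc),
             base_mean = res$base_mean,
             log2fc = res$log2fc,
             se = res$se,
             p = res$p,
             padj = padj,
             activity_class = classify_allele(res$log2fc, padj, thresholds),
             flagged = res$flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Roll allele calls up to variants and flag cross-cell-line contradictions
#'
#' A variant is an enhancer (silencer) variant in a cell line if any of its
#' alleles is an enhancer (silencer) allele there. A (variant, allele) called
#' enhancer in one cell line and silencer in another is flagged contradictory
#' and excluded from downstream allelic analysis.
#'
#' @param activity allele-level results (rbind of [call_activity()] across
#'   cell lines).
#' @return list(variant_classes = data.frame(cell_line, variant_id, enhancer,
#'   silencer), contradictory = data.frame(variant_id, allele)).
#' @export
rollup_variants <- function(activity) {
  key <- paste(activity$cell_line, activity$variant_id, sep = "\r")
  enh <- tapply(activity$activity_class == "enhancer", key, any)
  sil <- tapply(activity$activity_class == "silencer", key, any)
  parts <- strsplit(names(enh), "\r", fixed = TRUE)
  vc <- data.frame(cell_line = vapply(parts, `[[`, character(1), 1L),
                   variant_id = vapply(parts, `[[`, character(1), 2L),
                   enhancer = as.logical(enh),
                   silencer = as.logical(sil),
                   stringsAsFactors = FALSE, row.names = NULL)

  akey <- paste(activity$variant_id, activity$allele, sep = "\r")
  cls <- split(activity$activity_class, akey)
  contra <- vapply(cls, function(k)
    any(k == "enhancer") && any(k == "silencer"), logical(1))
  cp <- strsplit(names(cls)[contra], "\r", fixed = TRUE)
  contradictory <- data.frame(
    variant_id = vapply(cp, `[[`, character(1), 1L),
    allele = vapply(cp, `[[`, character(1), 2L),
    stringsAsFactors = FALSE)
  list(variant_classes = vc, contradictory = contradictory)
}
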