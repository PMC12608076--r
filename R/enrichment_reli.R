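# Resampling-based enrichment of variant sets in ChIP-seq peak datasets.
# The observed number of input variants falling inside a dataset's peaks is
# compared against a null built by repeatedly drawing equally sized variant
# sets from a negative set (the full MPRA library).

#' Count variants overlapping a peak set
#'
#' A variant (1-based position) overlaps if it lies inside any interval of
#' the peak set (BED convention: 0-based half-open, so position p overlaps
#' [start, end) iff start < p <= end). Each variant counts at most once.
#' Variants on chromosomes absent from the peak set do not overlap (a
#' warning is emitted for chromosomes never seen).
#'
#' @param variants data.frame(variant_id, chrom, pos) with 1-based positions.
#' @param peaks data.frame(chrom, start, end), 0-based half-open.
#' @return integer overlap count.
#' @export
overlap_count <- function(variants, peaks) {
  sum(overlap_indicator(variants, peaks))
}

#' Per-variant overlap indicator against a peak set
#'
#' @inheritParams overlap_count
#' @return named logical vector (names = variant_id).
#' @export
overlap_indicator <- function(variants, peaks) {
  out <- setNames(rep(FALSE, nrow(variants)), variants$variant_id)
  if (nrow(peaks) == 0L || nrow(variants) == 0L) return(out)
  unknown <- !(variants$chrom %in% unique(peaks$chrom))
  if (any(unknown) && !all(unknown))
    warning(sum(unknown), " variants on chromosomes absent from the peak set")
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1L))
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  out[] <- GenomicRanges::countOverlaps(vg, pg) > 0L
  out
}

#' Resampling enrichment test for one peak dataset
#'
#' Observed overlap of the input set vs a null of `iterations` draws of
#' equally sized sets sampled uniformly without replacement from the
#' negative set. Reports the null mean/sd, a z-score and the add-one
#' empirical p-value `(1 + #{draws >= observed}) / (iterations + 1)`.
#'
#' @param input_ids variant ids of the input set (must be contained in the
#'   negative set).
#' @param negative_ids variant ids of the negative set.
#' @param variants coordinate table (variant_id, chrom, pos) covering the
#'   negative set.
#' @param peaks one peak dataset (data.frame chrom, start, end).
#' @param iterations number of null draws (>= 100).
#' @param seed integer seed for the null draws.
#' @return data.frame(n_input, observed_overlap, null_mean, null_sd, z,
#'   p_empirical).
#' @export
reli_test <- function(input_ids, negative_ids, variants, peaks,
                      iterations = 2000L, seed = 1L) {
  if (iterations < 100L) stop("iterations must be >= 100")
  if (!all(input_ids %in% negative_ids))
    stop("input set must be contained in the negative set")
  if (length(input_ids) > length(negative_ids))
    stop("input set larger than negative set")
  vv <- variants[match(negative_ids, variants$variant_id), , drop = FALSE]
  if (anyNA(vv$variant_id))
    stop("negative-set variants missing coordinates")
  ind <- overlap_indicator(vv, peaks)
  observed <- sum(ind[match(input_ids, negative_ids)])
  n <- length(input_ids)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- vapply(seq_len(iterations),
                  function(i) sum(ind[sample.int(length(ind), n)]),
                  numeric(1))
  null_sd <- max(sd(draws), 1e-9)
  data.frame(n_input = n,
             observed_overlap = observed,
             null_mean = mean(draws),
             null_sd = null_sd,
             z = (observed - mean(draws)) / null_sd,
             p_empirical = (1 + sum(draws >= observed)) / (iterations + 1))
}

#' Enrichment battery over variant sets and peak datasets
#'
#' Runs [reli_test()] for every (input set x peak dataset) combination,
#' Bonferroni-corrects across datasets within each input set, and sorts by
#' empirical p within set.
#'
#' @param input_sets named list of variant-id vectors (e.g. enhancer,
#'   silencer, allelic_enhancer, allelic_silencer).
#' @param negative_ids the negative set (full library).
#' @param variants coordinate table.
#' @param peak_sets named list of peak data.frames.
#' @param iterations,seed passed to [reli_test()]; each (set, dataset) gets
#'   a deterministic child seed.
#' @return data.frame with input_set, dataset_id and the [reli_test()]
#'   columns plus p_corrected.
#' @export
run_battery <- function(input_sets, negative_ids, variants, peak_sets,
                        iterations = 2000L, seed = 1L) {
  if (length(peak_sets) == 0L) stop("at least one peak dataset required")
  rows <- list()
  for (sname in names(input_sets)) {
    for (dname in names(peak_sets)) {
      r <- reli_test(input_sets[[sname]], negative_ids, variants,
                     peak_sets[[dname]], iterations,
                     seed = child_seed(seed, paste(sname, dname)))
      rows[[length(rows) + 1L]] <-
        data.frame(input_set = sname, dataset_id = dname, r,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_corrected <- NA_real_
  for (sname in unique(out$input_set)) {
    i <- out$input_set == sname
    out$p_corrected[i] <- pmin(out$p_empirical[i] * sum(i), 1)
  }
  out <- out[order(out$input_set, out$p_empirical), , drop = FALSE]
  rownames(out) <- NULL
  out
}
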