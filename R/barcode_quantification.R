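# Per-sample barcode counting from single-end tag reads. A tag read is the
# 20-bp barcode followed by the constant region of the reporter 3' UTR;
# reads are kept when the constant window is within Levenshtein distance 4
# of the reference constant region and the two bases adjacent to the
# barcode match exactly.

#' Default constant region downstream of the barcode in tag reads
#' @export
CONSTANT_REGION <- "TCTAGAGTCGGGGCGGCCGGCCGCTTCGAG"

#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion edit distance. Vectorized over
#' `a` (recycled against `b`).
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
lev_dist <- function(a, b) {
  if (length(b) == 1L) return(as.integer(utils::adist(a, b)))
  if (length(a) == 1L) return(as.integer(utils::adist(b, a)))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(utils::adist(a[i], b[i])),
         integer(1))
}

#' Filter tag reads on the constant region
#'
#' Accepts a read iff the constant window (the stretch directly after the
#' 20-bp barcode, same length as the reference) is within `max_dist`
#' Levenshtein distance of the reference constant region AND the two bases
#' directly adjacent to the barcode match the reference exactly.
#'
#' @param reads data.frame(id, seq, qual) of tag reads (already
#'   quality-trimmed; see [quality_trim()] with the quantification flags
#'   LEADING:3 / TRAILING:3 / MINLEN:70).
#' @param constant_ref reference constant-region sequence (length >= 2).
#' @param max_dist maximum Levenshtein distance in the constant window.
#' @return list(accepted = data.frame of kept reads, reasons = named integer
#'   vector over {too_short, junction, constant_dist}, n_accepted).
#' @export
filter_tag_reads <- function(reads, constant_ref = CONSTANT_REGION,
                             max_dist = 4L) {
  if (nchar(constant_ref) < 2L) stop("constant_ref shorter than 2")
  lc <- nchar(constant_ref)
  need <- BARCODE_LEN + lc
  long_enough <- nchar(reads$seq) >= need
  windows <- substr(reads$seq, BARCODE_LEN + 1L, BARCODE_LEN + lc)
  junction_ok <- substr(reads$seq, BARCODE_LEN + 1L, BARCODE_LEN + 2L) ==
    substr(constant_ref, 1L, 2L)
  # Levenshtein only for non-identical windows (identical => distance 0)
  dist_ok <- windows == constant_ref
  todo <- which(long_enough & junction_ok & !dist_ok)
  if (length(todo))
    dist_ok[todo] <- lev_dist(windows[todo], constant_ref) <= max_dist
  accept <- long_enough & junction_ok & dist_ok
  reasons <- c(too_short = sum(!long_enough),
               junction = sum(long_enough & !junction_ok),
               constant_dist = sum(long_enough & junction_ok & !dist_ok))
  list(accepted = reads[accept, , drop = FALSE],
       reasons = reasons,
       n_accepted = sum(accept))
}

#' Count barcodes in accepted tag reads
#'
#' Exact-match lookup of the first 20 bases against the barcode map; reads
#' whose barcode is not in the map are tallied as unmapped.
#'
#' @param accepted data.frame of accepted reads (see [filter_tag_reads()]).
#' @param map barcode map data.frame with a `barcode` column.
#' @return list(counts = named integer vector over all map barcodes,
#'   n_unmapped).
#' @export
count_barcodes <- function(accepted, map) {
  bc <- substr(accepted$seq, 1L, BARCODE_LEN)
  idx <- match(bc, map$barcode)
  counts <- setNames(integer(nrow(map)), map$barcode)
  if (length(idx)) {
    tab <- tabulate(idx[!is.na(idx)], nbins = nrow(map))
    counts[] <- tab
  }
  list(counts = counts, n_unmapped = sum(is.na(idx)))
}

#' Quantify one sample from tag reads
#'
#' Convenience driver: quality trim with the quantification flags, filter on
#' the constant region, and count barcodes.
#'
#' @param reads raw tag reads data.frame(id, seq, qual).
#' @param map barcode map.
#' @param constant_ref constant-region reference.
#' @param leading_q,trailing_q,min_len quantification trimming parameters.
#' @param max_dist Levenshtein budget.
#' @return list(counts, qc = list of tallies).
#' @export
quantify_sample <- function(reads, map, constant_ref = CONSTANT_REGION,
                            leading_q = 3L, trailing_q = 3L, min_len = 70L,
                            max_dist = 4L) {
  tr <- quality_trim(reads, leading_q, trailing_q, min_len)
  fl <- filter_tag_reads(tr$reads, constant_ref, max_dist)
  ct <- count_barcodes(fl$accepted, map)
  list(counts = ct$counts,
       qc = list(n_reads = nrow(reads),
                 n_trim_discarded = tr$n_discarded,
                 reject_reasons = fl$reasons,
                 n_accepted = fl$n_accepted,
                 n_unmapped = ct$n_unmapped,
                 n_counted = fl$n_accepted - ct$n_unmapped))
}

#' Aggregate barcode-level counts to oligo level
#'
#' Oligo counts are the per-sample sums of their barcodes' counts; column
#' sums are conserved. Also retains per-oligo unique-barcode detection counts
#' (barcodes with nonzero count per sample) used by downstream filters.
#'
#' @param bc_counts integer matrix, rows = barcodes (rownames set), columns =
#'   samples.
#' @param map barcode map (barcode, oligo_id).
#' @param design_oligo_ids all designed oligo ids; absent oligos get zero
#'   rows.
#' @return list(counts = oligo x sample matrix, barcodes_detected = matrix of
#'   per-sample nonzero-barcode counts, n_barcodes = per-oligo mapped barcode
#'   totals).
#' @export
aggregate_to_oligo <- function(bc_counts, map, design_oligo_ids = NULL) {
  if (is.null(rownames(bc_counts))) stop("bc_counts must have barcode rownames")
  oligo <- map$oligo_id[match(rownames(bc_counts), map$barcode)]
  if (anyNA(oligo))
    stop("barcode in counts but not in map: ",
         rownames(bc_counts)[is.na(oligo)][1L])
  agg <- rowsum(bc_counts, group = oligo)
  det <- rowsum((bc_counts > 0L) + 0L, group = oligo)
  nbc <- as.integer(table(oligo)[rownames(agg)])
  if (!is.null(design_oligo_ids)) {
    out <- matrix(0L, nrow = length(design_oligo_ids), ncol = ncol(bc_counts),
                  dimnames = list(design_oligo_ids, colnames(bc_counts)))
    out[rownames(agg), ] <- agg
    det_full <- matrix(0L, nrow = length(design_oligo_ids),
                       ncol = ncol(bc_counts),
                       dimnames = list(design_oligo_ids, colnames(bc_counts)))
    det_full[rownames(det), ] <- det
    nbc_full <- setNames(integer(length(design_oligo_ids)), design_oligo_ids)
    nbc_full[rownames(agg)] <- nbc
    return(list(counts = out, barcodes_detected = det_full,
                n_barcodes = nbc_full))
  }
  list(counts = agg, barcodes_detected = det,
       n_barcodes = setNames(nbc, rownames(agg)))
}
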