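# Barcode-to-oligo association from paired-end reads of the cloned library.
# Read 1 carries a 20-bp degenerate barcode followed by the 5' end of the
# oligo; read 2 reads into the oligo from the other side. Association maps
# each mate pair back to the designed oligo sequences.

BARCODE_LEN <- 20L

#' Quality-trim reads from both ends
#'
#' Removes bases below the quality threshold from the leading and trailing
#' ends of each read (Phred+33), then discards reads shorter than `min_len`
#' (Trimmomatic LEADING/TRAILING/MINLEN semantics).
#'
#' @param reads data.frame(id, seq, qual).
#' @param leading_q,trailing_q minimum quality kept at each end.
#' @param min_len minimum post-trim length; shorter reads are discarded.
#' @return list(reads = trimmed data.frame, n_discarded = count).
#' @export
quality_trim <- function(reads, leading_q = 25L, trailing_q = 25L,
                         min_len = 80L) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("malformed FASTQ record: sequence/quality length mismatch at record ",
         which(nchar(reads$seq) != nchar(reads$qual))[1L])
  n <- nrow(reads)
  if (n == 0L) return(list(reads = reads, n_discarded = 0L))

  # quality chars with score >= q span [chr(33+q), chr(126)] in Phred+33
  qcls <- function(q) sprintf("[\\x%02X-\\x7E]", 33L + q)
  first_ge <- function(qual, q) {
    as.integer(regexpr(qcls(q), qual, perl = TRUE))
  }
  last_ge <- function(qual, q) {
    m <- regexpr(paste0("^.*", qcls(q)), qual, perl = TRUE)
    ifelse(m == -1L, -1L, attr(m, "match.length"))
  }
  from <- first_ge(reads$qual, leading_q)
  to <- last_ge(reads$qual, trailing_q)
  ok <- from > 0L & to > 0L & (to - from + 1L) >= min_len
  out <- reads[ok, , drop = FALSE]
  out$seq <- substr(out$seq, from[ok], to[ok])
  out$qual <- substr(out$qual, from[ok], to[ok])
  rownames(out) <- NULL
  list(reads = out, n_discarded = n - nrow(out))
}

#' Split read 1 into barcode and oligo-matching region
#'
#' The first 20 bases are the degenerate barcode; the remainder matches the
#' oligo. Reads too short to leave a `min_region` oligo region, or whose
#' barcode contains N, are dropped and counted.
#'
#' @param reads data.frame(id, seq, qual) (read 1, already trimmed).
#' @param min_region minimum length of the oligo-matching region.
#' @return list(barcode, oligo_region, id — parallel vectors for kept reads;
#'   n_short, n_barcode_n — drop tallies).
#' @export
split_read1 <- function(reads, min_region = 15L) {
  len <- nchar(reads$seq)
  long_enough <- len >= BARCODE_LEN + min_region
  bc <- toupper(substr(reads$seq, 1L, BARCODE_LEN))
  clean <- !grepl("N", bc, fixed = TRUE)
  keep <- long_enough & clean
  list(barcode = bc[keep],
       oligo_region = substr(reads$seq[keep], BARCODE_LEN + 1L, len[keep]),
       id = reads$id[keep],
       n_short = sum(!long_enough),
       n_barcode_n = sum(long_enough & !clean))
}

#' Build an oligo matching index
#'
#' Indexes the designed full oligo sequences for prefix (read-1 oligo region)
#' and suffix (read 2) matching with a per-mate substitution budget.
#'
#' @param designs design data.frame with oligo_id and full columns.
#' @return an opaque index object for [match_oligo()].
#' @export
build_oligo_index <- function(designs) {
  if (nrow(designs) == 0L) stop("empty oligo index")
  idx <- new.env(parent = emptyenv())
  idx$oligo_id <- designs$oligo_id
  idx$full <- designs$full
  idx$cache <- new.env(parent = emptyenv())  # per-length split matrices
  class(idx) <- "oligo_index"
  idx
}

# character matrix of prefixes (or suffixes) of the indexed oligos, cached
.index_mat <- function(index, len, side) {
  key <- paste0(side, len)
  if (!is.null(index$cache[[key]])) return(index$cache[[key]])
  seqs <- if (side == "p") substr(index$full, 1L, len) else
    substr(index$full, nchar(index$full) - len + 1L, nchar(index$full))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              ncol = len, byrow = TRUE)
  index$cache[[key]] <- list(seqs = seqs, mat = m)
  index$cache[[key]]
}

# substitution distance of one string against all indexed prefixes/suffixes
.sub_dist <- function(index, s, side) {
  len <- nchar(s)
  ref <- .index_mat(index, len, side)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  len - (ref$mat == matrix(ch, nrow = nrow(ref$mat), ncol = len,
                           byrow = TRUE)) %*% rep(1, len)
}

#' Match a mate pair to its oligo
#'
#' Returns the oligo whose sequence contains both mates within the
#' substitution budget (no indels): the read-1 oligo region against the
#' oligo 5' end and the reverse complement of read 2 against the 3' end.
#' `NA` when no oligo fits or when more than one fits equally well
#' (ambiguous, e.g. the allele base was not read).
#'
#' @param oligo_region oligo-matching part of read 1.
#' @param read2 read-2 sequence (as sequenced, reverse strand).
#' @param index from [build_oligo_index()].
#' @param max_mm per-mate substitution budget.
#' @return oligo_id or NA_character_.
#' @export
match_oligo <- function(oligo_region, read2, index, max_mm = 2L) {
  if (!inherits(index, "oligo_index")) stop("index must be an oligo_index")
  d1 <- .sub_dist(index, oligo_region, "p")
  d2 <- .sub_dist(index, revcomp(read2), "s")
  ok <- which(d1 <= max_mm & d2 <= max_mm)
  if (length(ok) == 0L) return(NA_character_)
  tot <- d1[ok] + d2[ok]
  best <- ok[tot == min(tot)]
  if (length(best) != 1L) return(NA_character_)
  index$oligo_id[best]
}

# bulk association: exact hash lookup first, substitution fallback for the
# rest; ambiguity (several oligos fitting equally) yields NA
match_oligo_bulk <- function(oligo_regions, read2s, index, max_mm = 2L) {
  n <- length(oligo_regions)
  out <- rep(NA_character_, n)
  r2rc <- revcomp(read2s)
  l1 <- nchar(oligo_regions)
  l2 <- nchar(r2rc)
  for (lens in split(seq_len(n), paste(l1, l2))) {
    L1 <- l1[lens[1L]]; L2 <- l2[lens[1L]]
    pre <- substr(index$full, 1L, L1)
    suf <- substr(index$full, nchar(index$full) - L2 + 1L, nchar(index$full))
    key <- paste0(pre, "|", suf)
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    lut <- ifelse(dup, NA_character_, index$oligo_id)
    hit <- match(paste0(oligo_regions[lens], "|", r2rc[lens]), key)
    exact <- !is.na(hit)
    out[lens[exact]] <- lut[hit[exact]]
    for (i in lens[!exact]) {
      out[i] <- match_oligo(oligo_regions[i], read2s[i], index,
                            max_mm = max_mm)
    }
  }
  out
}

#' Associate barcodes with oligos from paired-end reads
#'
#' Full association stage: quality trim both mates, split read 1 into barcode
#' and oligo region, match mate pairs against the design, and collect
#' (barcode, oligo_id) associations.
#'
#' @param read1,read2 data.frames(id, seq, qual) with matching ids.
#' @param index from [build_oligo_index()].
#' @param leading_q,trailing_q,min_len trimming parameters.
#' @param max_mm per-mate substitution budget for matching.
#' @return list(associations = data.frame(barcode, oligo_id), log = list of
#'   tallies).
#' @export
associate_barcodes <- function(read1, read2, index,
                               leading_q = 25L, trailing_q = 25L,
                               min_len = 80L, max_mm = 2L) {
  t1 <- quality_trim(read1, leading_q, trailing_q, min_len)
  t2 <- quality_trim(read2, leading_q, trailing_q, min_len)
  # keep pairs where both mates survive trimming
  common <- intersect(t1$reads$id, t2$reads$id)
  r1 <- t1$reads[match(common, t1$reads$id), , drop = FALSE]
  r2 <- t2$reads[match(common, t2$reads$id), , drop = FALSE]
  sp <- split_read1(r1)
  r2k <- r2$seq[match(sp$id, r2$id)]
  oligo <- match_oligo_bulk(sp$oligo_region, r2k, index, max_mm = max_mm)
  hit <- !is.na(oligo)
  list(associations = data.frame(barcode = sp$barcode[hit],
                                 oligo_id = oligo[hit],
                                 stringsAsFactors = FALSE),
       log = list(n_pairs_in = nrow(read1),
                  n_pairs_trimmed_out = nrow(read1) - length(common),
                  n_read1_short = sp$n_short,
                  n_barcode_n = sp$n_barcode_n,
                  n_unmatched = sum(!hit),
                  n_associated = sum(hit)))
}

#' Build the barcode map from raw associations
#'
#' Per barcode, keeps the modal oligo when its purity (modal fraction) and
#' read support pass the thresholds; conflicted or weakly supported barcodes
#' are discarded.
#'
#' @param associations data.frame(barcode, oligo_id).
#' @param min_support minimum reads supporting the modal oligo.
#' @param min_purity minimum modal fraction.
#' @return list(map = data.frame(barcode, oligo_id, support_reads, purity),
#'   n_discarded_support, n_discarded_purity).
#' @export
build_barcode_map <- function(associations, min_support = 2L,
                              min_purity = 0.9) {
  stopifnot(min_purity > 0.5, min_purity <= 1)
  if (nrow(associations) == 0L)
    return(list(map = data.frame(barcode = character(0),
                                 oligo_id = character(0),
                                 support_reads = integer(0),
                                 purity = numeric(0)),
                n_discarded_support = 0L, n_discarded_purity = 0L))
  key <- paste0(associations$barcode, "\r", associations$oligo_id)
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  df <- data.frame(barcode = vapply(parts, `[[`, character(1), 1L),
                   oligo_id = vapply(parts, `[[`, character(1), 2L),
                   n = as.integer(tab), stringsAsFactors = FALSE)
  ord <- order(df$barcode, -df$n, df$oligo_id)
  df <- df[ord, , drop = FALSE]
  first <- !duplicated(df$barcode)
  total <- rowsum(df$n, df$barcode)  # sorted by barcode
  modal <- df[first, , drop = FALSE]
  tot <- total[match(modal$barcode, rownames(total)), 1L]
  purity <- modal$n / tot
  keep_sup <- modal$n >= min_support
  keep_pur <- purity >= min_purity
  keep <- keep_sup & keep_pur
  map <- data.frame(barcode = modal$barcode[keep],
                    oligo_id = modal$oligo_id[keep],
                    support_reads = modal$n[keep],
                    purity = purity[keep],
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  list(map = map,
       n_discarded_support = sum(!keep_sup),
       n_discarded_purity = sum(keep_sup & !keep_pur))
}

#' Per-oligo barcode statistics
#'
#' Counts unique barcodes per oligo, reporting the median both over oligos
#' observed in the map and over the full design (absent oligos zero-filled).
#'
#' @param map barcode map data.frame (barcode, oligo_id).
#' @param design_oligo_ids optional character vector of all designed oligo
#'   ids for zero-filling.
#' @return list(per_oligo = data.frame(oligo_id, n_barcodes),
#'   median_observed, median_design).
#' @export
map_stats <- function(map, design_oligo_ids = NULL) {
  if (nrow(map) == 0L) stop("no associations")
  tab <- table(map$oligo_id)
  per <- data.frame(oligo_id = names(tab), n_barcodes = as.integer(tab),
                    stringsAsFactors = FALSE)
  med_obs <- median(per$n_barcodes)
  med_des <- NA_real_
  if (!is.null(design_oligo_ids)) {
    full <- setNames(integer(length(design_oligo_ids)), design_oligo_ids)
    full[per$oligo_id] <- per$n_barcodes
    med_des <- median(full)
  }
  list(per_oligo = per, median_observed = med_obs, median_design = med_des)
}
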