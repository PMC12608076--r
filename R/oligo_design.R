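# Oligo library design: variant filters and construction of 170-bp cores
# wrapped by fixed 15-bp cloning adapters into 200-bp synthesis sequences.

#' Cloning adapter constants
#'
#' 15-bp adapters flanking every 170-bp core; the full synthesized oligo is
#' `ADAPTER5 + core + ADAPTER3` (200 bp). Adapters keep a fixed orientation;
#' only the core is reverse-complemented for the second orientation.
#' @export
ADAPTER5 <- "ACTGGCCGCTTGACG"

#' @rdname ADAPTER5
#' @export
ADAPTER3 <- "CACTGCGGCTCCTGC"

CORE_LEN <- 170L
SNP_UP <- 84L    # flanking bases upstream of the variant in a SNP core
SNP_DOWN <- 85L  # flanking bases downstream

#' Filter variant records for oligo synthesis
#'
#' Removes variants whose alleles cannot be synthesized reliably: any allele
#' longer than 10 bases (long indels) or containing a homopolymer run longer
#' than 4. Input order is preserved in both outputs.
#'
#' @param variants data.frame with columns variant_id, chrom, pos, ref_allele,
#'   alt_alleles (comma-separated string), and optionally locus_id, tier.
#' @param homopolymer_scope `"allele"` (default) screens allele sequences
#'   only; `"core"` is accepted for callers that pre-build cores and screen
#'   those instead.
#' @return list with elements `kept` (data.frame) and `removed`
#'   (data.frame with a `reason` column; reasons comma-joined when several
#'   apply).
#' @export
filter_variants <- function(variants, homopolymer_scope = c("allele", "core")) {
  homopolymer_scope <- match.arg(homopolymer_scope)
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "ref_allele", "alt_alleles") %in% names(variants)))
  alleles <- variant_alleles(variants)
  if (any(vapply(alleles, function(a)
    length(a) < 2L || any(!nzchar(a)), logical(1))))
    stop("empty allele in variant record")
  bad_chr <- vapply(alleles, function(a) any(grepl("[^ACGT]", a)), logical(1))
  if (any(bad_chr))
    stop("allele with non-ACGT characters: ",
         paste(variants$variant_id[bad_chr], collapse = ", "))

  too_long <- vapply(alleles, function(a) any(nchar(a) > 10L), logical(1))
  homopoly <- vapply(alleles, function(a)
    any(grepl("A{5,}|C{5,}|G{5,}|T{5,}", a)), logical(1))

  reason <- character(nrow(variants))
  reason[too_long] <- "indel_len_gt_10"
  reason[homopoly] <- ifelse(nzchar(reason[homopoly]),
                             paste0(reason[homopoly], ",homopolymer_gt_4"),
                             "homopolymer_gt_4")
  drop <- nzchar(reason)
  removed <- variants[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[drop] else removed$reason <- character(0)
  list(kept = variants[!drop, , drop = FALSE], removed = removed)
}

# alleles of each variant as a list: reference first, then alternates
variant_alleles <- function(variants) {
  alts <- strsplit(as.character(variants$alt_alleles), ",", fixed = TRUE)
  mapply(function(r, a) c(r, a), as.character(variants$ref_allele), alts,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Build one 170-bp oligo core
#'
#' For SNPs the core is the last 84 bases of the upstream flank, the allele
#' base, then the first 85 bases of the downstream flank, so the allele sits
#' at position 85 (1-based). For indel alleles the allele still starts at
#' offset 85 and the downstream contribution shrinks or grows so the core is
#' exactly 170 bp. Flanks are shared across the alleles of one variant.
#'
#' @param variant_id id used in error messages.
#' @param allele allele sequence (1 bp for SNPs).
#' @param flank_up upstream genomic flank, length >= 84.
#' @param flank_down downstream genomic flank, length >= 170 - 84 - 1.
#' @return core DNA string of length 170.
#' @export
build_core <- function(variant_id, allele, flank_up, flank_down) {
  la <- nchar(allele)
  if (la < 1L) stop("empty allele for ", variant_id)
  down_need <- CORE_LEN - SNP_UP - la
  if (down_need < 0L)
    stop("allele longer than core window for ", variant_id)
  if (nchar(flank_up) < SNP_UP || nchar(flank_down) < down_need)
    stop("insufficient flanking sequence for ", variant_id)
  up <- substr(flank_up, nchar(flank_up) - SNP_UP + 1L, nchar(flank_up))
  down <- substr(flank_down, 1L, down_need)
  core <- paste0(up, allele, down)
  stopifnot(nchar(core) == CORE_LEN)
  core
}

#' Emit forward and reverse-complement oligo designs
#'
#' For every (variant, allele) two designs are produced: the forward core and
#' its reverse complement, each wrapped in the fixed adapters. Oligo ids
#' encode variant, allele role, allele and orientation, e.g.
#' `rs123_Ref_A_fwd`.
#'
#' @param variants kept variant data.frame (see [filter_variants()]).
#' @param flanks named list (by variant_id) of `list(up =, down =)` flank
#'   sequences; variants with no flank entry are recorded as removed with
#'   reason `"no_flank"`.
#' @return list with `designs` (data.frame oligo_id, variant_id, allele,
#'   allele_role, orientation, core, full) and `removed` (data.frame
#'   variant_id, reason).
#' @export
emit_oligos <- function(variants, flanks) {
  alleles <- variant_alleles(variants)
  no_flank <- !(variants$variant_id %in% names(flanks))
  removed <- data.frame(variant_id = variants$variant_id[no_flank],
                        reason = rep("no_flank", sum(no_flank)),
                        stringsAsFactors = FALSE)
  keep <- which(!no_flank)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    vid <- variants$variant_id[k]
    fl <- flanks[[vid]]
    als <- alleles[[k]]
    roles <- c("Ref", paste0("Alt", seq_len(length(als) - 1L)))
    sub <- vector("list", length(als))
    for (j in seq_along(als)) {
      core <- build_core(vid, als[j], fl$up, fl$down)
      core_rc <- revcomp(core)
      sub[[j]] <- data.frame(
        oligo_id = paste(vid, roles[j], als[j], c("fwd", "rc"), sep = "_"),
        variant_id = vid,
        allele = als[j],
        allele_role = roles[j],
        orientation = c("forward", "revcomp"),
        core = c(core, core_rc),
        full = paste0(ADAPTER5, c(core, core_rc), ADAPTER3),
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, sub)
  }
  designs <- do.call(rbind, rows)
  if (is.null(designs))
    designs <- data.frame(oligo_id = character(0), variant_id = character(0),
                          allele = character(0), allele_role = character(0),
                          orientation = character(0), core = character(0),
                          full = character(0), stringsAsFactors = FALSE)
  if (anyDuplicated(designs$oligo_id))
    stop("duplicate oligo_id in design: ",
         designs$oligo_id[duplicated(designs$oligo_id)][1L])
  rownames(designs) <- NULL
  list(designs = designs, removed = removed)
}
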