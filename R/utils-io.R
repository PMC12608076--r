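#' @importFrom stats median p.adjust pnorm pt rnbinom rpois rlnorm runif
#'   rbinom rnorm lm coef cor hclust cutree as.dist setNames sd ave
#'   fisher.test ks.test t.test uniroot quantile var
#' @importFrom utils read.delim write.table head tail
NULL

# ---- small sequence helpers -------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' Draws `n` sequences of length `len` uniformly over A/C/G/T. Uses the
#' current RNG state; callers set seeds.
#'
#' @param n number of sequences.
#' @param len sequence length.
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# ---- tabular I/O ------------------------------------------------------------

#' Read / write tab-separated tables
#'
#' All pipeline tables are TSV with a header row, UTF-8, no quoting.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_file` returns a data.frame.
#' @export
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_tsv_file
#' @export
write_tsv_file <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- FASTQ ------------------------------------------------------------------

#' Read / write FASTQ
#'
#' Reads are handled as plain data.frames with columns `id`, `seq`, `qual`
#' (Phred+33). Files may be gzip-compressed (by extension).
#'
#' @param path FASTQ path, optionally `.gz`.
#' @param reads data.frame with columns id, seq, qual.
#' @return `read_fastq` returns a data.frame(id, seq, qual).
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id   = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq  = toupper(lines[idx + 1L]),
             qual = lines[idx + 3L],
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  n <- nrow(reads)
  if (n > 0L) {
    out <- character(4L * n)
    out[seq(1L, 4L * n, 4L)] <- paste0("@", reads$id)
    out[seq(2L, 4L * n, 4L)] <- reads$seq
    out[seq(3L, 4L * n, 4L)] <- "+"
    out[seq(4L, 4L * n, 4L)] <- reads$qual
    writeLines(out, con)
  }
  invisible(path)
}

# ---- FASTA ------------------------------------------------------------------

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# ---- BED --------------------------------------------------------------------

#' Read / write BED3+name interval files
#'
#' Coordinates are 0-based half-open on disk, following BED convention.
#' In memory, peak sets are data.frames with columns chrom, start, end
#' (still 0-based half-open) plus optional name.
#'
#' @param path BED path.
#' @param peaks data.frame(chrom, start, end[, name]).
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4L] <- "name"
  if (any(x$start >= x$end)) stop("invalid BED interval (start >= end) in ", path)
  x
}

#' @rdname read_bed
#' @export
write_bed <- function(peaks, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cols <- intersect(c("chrom", "start", "end", "name"), names(peaks))
  write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- GMT --------------------------------------------------------------------

#' Read / write GMT gene-set files
#'
#' @param path GMT path (set name, description, then genes, tab-separated).
#' @param sets named list of character gene vectors.
#' @return `read_gmt` returns a named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- misc -------------------------------------------------------------------

# deterministic child seed derived from a user seed and a stage label;
# kept below 2^31 so it is a valid R integer
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483647)
}
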