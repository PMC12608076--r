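# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain recursion for edit distance, choose()-based tail
# enumeration for the hypergeometric, and the textbook step-up formula for
# BH.

# memoized textbook recursion for Levenshtein distance
lev_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(x, y) {
    if (nchar(x) == 0L) return(nchar(y))
    if (nchar(y) == 0L) return(nchar(x))
    key <- paste0(x, "|", y)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- as.integer(substr(x, 1L, 1L) != substr(y, 1L, 1L))
    xs <- substr(x, 2L, nchar(x)); ys <- substr(y, 2L, nchar(y))
    v <- min(rec(xs, y) + 1L, rec(x, ys) + 1L, rec(xs, ys) + cost)
    memo[[key]] <- v
    v
  }
  rec(a, b)
}

# one-sided (greater) Fisher p for table (a, b; c, d) by direct enumeration
# of the hypergeometric tail with choose()
fisher_tail_oracle <- function(a, b, c_, d) {
  n_list <- a + b      # genes in the list
  k_set <- a + c_      # genes in the set
  n_tot <- a + b + c_ + d
  kmax <- min(n_list, k_set)
  ks <- a:kmax
  sum(choose(k_set, ks) * choose(n_tot - k_set, n_list - ks)) /
    choose(n_tot, n_list)
}

# textbook BH step-up adjustment: p(i) * m / i, then right-to-left minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# all DNA strings of length 0..max_len
all_dna_strings <- function(max_len, alphabet = c("A", "C", "G", "T")) {
  out <- ""
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, do.call(paste0, grid))
  }
  out
}

# small default study used by several tests (cheap: ~330 oligos)
tiny_config <- function(...) {
  sim_config(n_variants = 60, n_loci = 10, barcodes_per_oligo_median = 20,
             depth_per_sample = 2e5, n_cell_lines = 2, seed = 7, ...)
}

# quality string helper
qs <- function(scores) intToUtf8(33L + scores)
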