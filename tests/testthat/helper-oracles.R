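# Independent oracles used across tests. Each is a deliberately naive
# implementation (string scans, exhaustive recursion, rank statistics)
# kept separate from the code paths it checks.

# sliding-window k-mer counter by direct string comparison
naive_kmer_count <- function(seq, kmer) {
  k <- nchar(kmer)
  n <- nchar(seq)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1),
             function(i) substr(seq, i, i + k - 1) == kmer, logical(1)))
}

# exhaustive maximum base-pair count over all nested structures
# (exponential recursion, usable for length <= 12)
bf_max_pairs <- function(seq, min_loop = 3L) {
  can_pair <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  chars <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)  # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (can_pair(chars[i], chars[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(chars) < 2) return(0L)
  rec(1L, length(chars))
}

# AUROC as the normalized Mann-Whitney U statistic
mw_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# double-loop cosine-series summation
fourier_oracle <- function(x, k = 10L) {
  L <- length(x)
  out <- numeric(k)
  for (kk in 0:(k - 1)) {
    s <- 0
    for (n in 0:(L - 1))
      s <- s + x[n + 1] * cos(pi / L * (n + 0.5) * (kk + 0.5))
    out[kk + 1] <- 2 / L * s
  }
  out
}

random_rna <- function(n) paste0(sample(c("A", "C", "G", "U"), n,
                                        replace = TRUE), collapse = "")
random_protein <- function(n) paste0(sample(lpipred::conjoint_groups() |>
                                              names(), n, replace = TRUE),
                                     collapse = "")

tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
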