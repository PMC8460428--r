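# Independent oracles used to cross-check the package implementation.
# These deliberately use naive algorithms (character-by-character scans,
# brute-force enumeration) and never share code with the package internals.

# naive exact-match localization: compare every target window with every
# fragment (and its reverse complement), one character run at a time
naive_locate <- function(frag_seqs, target, strand_mode = "both") {
  k <- nchar(frag_seqs[1])
  hits <- list()
  n_win <- nchar(target) - k + 1
  for (f in unique(frag_seqs)) {
    f_rc <- oracle_revcomp(f)
    for (p in seq_len(max(n_win, 0))) {
      win <- substr(target, p, p + k - 1)
      if (win == f)
        hits[[length(hits) + 1]] <- data.frame(pos = p - 1, strand = "+",
                                               fragment = f)
      if (strand_mode == "both" && f != f_rc && win == f_rc)
        hits[[length(hits) + 1]] <- data.frame(pos = p - 1, strand = "-",
                                               fragment = f)
    }
  }
  if (!length(hits)) return(data.frame(pos = numeric(0), strand = character(0),
                                       fragment = character(0)))
  do.call(rbind, hits)
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Spearman as rank-then-Pearson, written from the product-moment sums
rank_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx^2) - n * mean(rx)^2
  syy <- sum(ry^2) - n * mean(ry)^2
  sxy / sqrt(sxx * syy)
}

# tie-free closed form
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# longest common substring by brute-force enumeration of all substrings
lcs_brute <- function(a, b) {
  na <- nchar(a)
  for (len in seq(na, 1)) {
    for (s in seq_len(na - len + 1)) {
      if (grepl(substr(a, s, s + len - 1), b, fixed = TRUE)) return(len)
    }
  }
  0L
}

# exhaustive permutation p-value for the learning-index test
exact_li_p <- function(naive, trained) {
  pooled <- c(naive, trained)
  n1 <- length(naive)
  obs <- 100 * (mean(naive) - mean(trained)) / mean(naive)
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) {
    m_na <- mean(pooled[idx])
    if (m_na == 0) return(Inf)
    100 * (m_na - mean(pooled[-idx])) / m_na
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# random uppercase genome string
random_genome_seq <- function(len, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

as_genome <- function(...) {
  seqs <- c(...)
  structure(seqs, class = "genome_sequence")
}

# small synthetic spec shared by tests that need a fast full pipeline
small_spec <- function(seed = 7L)
  synthetic_genome_spec(n_bands = 10L, band_length = 20000L,
                        source_band = 3L, control_band = 8L, seed = seed)
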