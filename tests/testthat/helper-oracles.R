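# Independent oracle implementations, kept deliberately separate from the
# package's code paths: plain-R dynamic programming, exhaustive enumeration
# and closed-form arithmetic used to freeze expected values.

# quadratic-space Needleman-Wunsch in pure R: optimal score plus the
# maximum identity count over score-optimal alignments
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  I <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap
  S[1, ] <- (0:m) * gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- x[i] == y[j]
      cand <- c(S[i, j] + if (eq) match else mismatch,
                S[i, j + 1] + gap,
                S[i + 1, j] + gap)
      best <- max(cand)
      S[i + 1, j + 1] <- best
      ident <- -Inf
      if (cand[1] == best) ident <- max(ident, I[i, j] + eq)
      if (cand[2] == best) ident <- max(ident, I[i, j + 1])
      if (cand[3] == best) ident <- max(ident, I[i + 1, j])
      I[i + 1, j + 1] <- ident
    }
  }
  list(score = S[n + 1, m + 1], identities = I[n + 1, m + 1])
}

oracle_identity <- function(a, b) {
  oracle_nw(a, b)$identities / min(nchar(a), nchar(b))
}

oracle_similarity <- function(a, b) {
  pa <- fecalproteo::normalize_peptide(a)
  pb <- fecalproteo::normalize_peptide(b)
  100 * max(0, oracle_nw(pa, pb)$score) / max(nchar(pa), nchar(pb))
}

# hypergeometric upper tail P(X >= k) from choose() directly
oracle_hyper_tail <- function(k, K, n_draw, N) {
  j <- k:min(K, n_draw)
  if (length(j) == 0 || k > min(K, n_draw)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n_draw - j) - lchoose(N, n_draw)))
}

# exhaustive tryptic peptide enumeration over all cleavage-site subsets
oracle_digest <- function(sequence, mc_max, min_length = 6, max_length = 50) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n & aa[sites + 1] != "P"]
  bounds <- c(0, sites, n)
  out <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in (i + 1):length(bounds)) {
      n_internal <- j - i - 1
      if (n_internal > mc_max) next
      pep <- substr(sequence, bounds[i] + 1, bounds[j])
      if (nchar(pep) >= min_length && nchar(pep) <= max_length) {
        out <- c(out, pep)
      }
    }
  }
  sort(unique(out))
}

# random amino-acid sequence (test-local, independent of the generator)
rand_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}
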