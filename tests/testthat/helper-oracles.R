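# Independent oracles used to validate the package implementations.

# Brute-force affine-gap Smith-Waterman score; gap of length k costs
# gap_open + k * gap_ext. Pure R, quadratic time, independent of src/sw.cpp.
sw_oracle_score <- function(a, b, match = 2, mismatch = -2,
                            gap_open = 5, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Global-alignment identity oracle through Biostrings: unit-cost
# Needleman-Wunsch (match 0, mismatch -1, gap -1) gives -score = edit
# distance; identity = 1 - edit/max(length).
identity_oracle <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  1 - (-Biostrings::score(aln)) / max(nchar(a), nchar(b))
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group labelings (no ties assumed).
mw_enumeration_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  r <- rank(vals)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(vals), n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# patterns (no zero differences, no tied magnitudes assumed).
wsr_enumeration_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Spearman rho oracle: rank transform then product-moment correlation.
spearman_oracle_rho <- function(x, y) stats::cor(rank(x), rank(y))

random_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")
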