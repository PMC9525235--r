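# Independent oracles used by the tests; deliberately simple, brute-force
# implementations that share no code with the package internals.

# Plain affine-gap Smith-Waterman DP (gap of length L costs open + L*extend)
sw_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62_oracle <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Brute-force connected components by label propagation
components_oracle <- function(nodes, edges) {
  lab <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$id_a[k]
      b <- edges$id_b[k]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[a] <- m
        lab[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}
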