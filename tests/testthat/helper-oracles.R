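# Independent oracles used to cross-check the package's alignment paths.

# Levenshtein distance via base R (C implementation in utils::adist),
# independent of the seeded-anchor + gap-fill aligner.
edit_distance_oracle <- function(a, b) {
  drop(utils::adist(a, b))
}

# identity implied by the optimal unit-cost alignment, on instances where
# substitutions dominate: 1 - d / L with L the longer sequence
dp_identity_oracle <- function(query, target) {
  1 - edit_distance_oracle(query, target) / max(nchar(query), nchar(target))
}

# Pure-R affine-gap local (Smith-Waterman) alignment score maximization,
# mirroring the scoring convention score(gap of length L) = -(open + L*ext).
# Independent of the Biostrings-backed implementation path.
affine_local_score_oracle <- function(p, q, mat, open = 10, ext = 0.5) {
  pc <- strsplit(p, "")[[1]]
  qc <- strsplit(q, "")[[1]]
  n <- length(pc); m <- length(qc)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[pc[i], qc[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# mutate a DNA string with substitutions (and optionally short indels)
mutate_dna <- function(x, sub_rate = 0.05, indel_rate = 0) {
  ch <- strsplit(x, "")[[1]]
  n <- length(ch)
  nsub <- rbinom(1, n, sub_rate)
  if (nsub > 0) {
    at <- sample.int(n, nsub)
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  if (indel_rate > 0) {
    nind <- rbinom(1, n, indel_rate)
    for (k in seq_len(nind)) {
      at <- sample.int(length(ch), 1)
      if (runif(1) < 0.5) ch <- ch[-at]
      else ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = at)
    }
  }
  paste(ch, collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
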