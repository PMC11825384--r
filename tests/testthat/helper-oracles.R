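# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive and separate from the package's own code paths.

BASES <- c("A", "C", "G", "T")

# all DNA sequences of length n, lexicographic
all_seqs <- function(n) {
  out <- ""
  for (i in seq_len(n)) out <- paste0(rep(out, each = 4L), BASES)
  out
}

# memoised recursive edit distance (unit costs); independent of utils::adist
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- matrix(NA_integer_, length(ca) + 1L, length(cb) + 1L)
  f <- function(i, j) {  # distance between ca[i..] and cb[j..]
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i > length(ca)) length(cb) - j + 1L
    else if (j > length(cb)) length(ca) - i + 1L
    else min(f(i + 1L, j) + 1L,
             f(i, j + 1L) + 1L,
             f(i + 1L, j + 1L) + (ca[i] != cb[j]))
    memo[i, j] <<- v
    v
  }
  f(1L, 1L)
}

# The functional-group reference table restated from first principles
# (Watson-Crick edge chemistry, groups read 5'->3' across the pair), and the
# substitution costs it induces, recomputed by brute force.
oracle_groups <- local({
  major <- list(A = c("ACCEPTOR", "DONOR", "ACCEPTOR", "METHYL"),
                G = c("ACCEPTOR", "ACCEPTOR", "DONOR", "NONPOLAR_H"))
  major$T <- rev(major$A); major$C <- rev(major$G)
  minor <- list(A = c("ACCEPTOR", "NONPOLAR_H", "ACCEPTOR"),
                G = c("ACCEPTOR", "DONOR", "ACCEPTOR"))
  minor$T <- rev(minor$A); minor$C <- rev(minor$G)
  list(major = major, minor = minor)
})

oracle_physchem_cost <- function(a, b) {
  # each differing group contributes 2 (two one-hot slots flip)
  2L * (sum(oracle_groups$major[[a]] != oracle_groups$major[[b]]) +
        sum(oracle_groups$minor[[a]] != oracle_groups$minor[[b]]))
}

oracle_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# full pairwise distance matrix over a set of equal-length sequences, from a
# 4x4 per-position cost matrix (vectorised; used for exhaustive axiom checks)
pairwise_dist_matrix <- function(seqs, cost) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  D <- matrix(0, length(seqs), length(seqs))
  for (p in seq_len(ncol(chars)))
    D <- D + cost[chars[, p], chars[, p]]
  dimnames(D) <- NULL
  D
}

# hand-built shape_profile (for metric unit tests that bypass the predictor)
fake_profile <- function(n, ...) {
  vals <- list(...)
  for (f in names(vals)) {
    len <- length(vals[[f]])
    names(vals[[f]]) <- as.character(seq_len(len))
  }
  structure(vals, n = n, edge_policy = "mean", class = "shape_profile")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
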