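# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# Quadratic Smith-Waterman with affine gaps (gap of length k costs
# open + k * ext), returning only the best score.
sw_bruteforce <- function(query, target, match = 1, mismatch = -1,
                          open = 2, ext = 1) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(t)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)  # gap in target (consumes query)
  Iy <- matrix(-Inf, n + 1, m + 1)  # gap in query (consumes target)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (q[i - 1] == t[j - 1] && q[i - 1] != "N") match else mismatch
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exhaustive single-linkage clustering oracle: connected components of the
# graph joining anchors within `window` on the same chromosome.
cluster_oracle <- function(chrom, pos, window) {
  n <- length(pos)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(pos[i] - pos[j]) <= window)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      new <- min(comp[linked])
      if (any(comp[linked] != new)) {
        comp[linked] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Exhaustive merge oracle: connected components of the interval graph on
# calls (within `window`), keeping the best call per component under the
# (filter_level, total support, leftmost) key.
merge_oracle <- function(calls, window) {
  comp <- cluster_oracle(calls$chrom, calls$breakpoint_pos, window)
  keep <- vapply(unique(comp), function(cc) {
    ix <- which(comp == cc)
    key <- order(-calls$filter_level[ix],
                 -(calls$support_5p[ix] + calls$support_3p[ix]),
                 calls$breakpoint_pos[ix])
    ix[key[1]]
  }, integer(1))
  out <- calls[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate a sequence with k random substitutions.
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
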