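# Independent brute-force oracles used to cross-check the package's
# alignment, edit-distance, and phylogeny code. Deliberately simple nested
# loops, no shared code with the implementation.

# Affine-gap global alignment score (Gotoh, gap of length L costs
# open + L * ext), plus the match/column identity of one optimal traceback.
nw_oracle <- function(a, b, match = 1, mismatch = -1, open = 4, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                      Iy[i - 1, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                      Ix[i, j - 1] - open - ext)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback for identity (any one optimal path)
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1 && i > 1 && j > 1) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      if (x[i - 1] == y[j - 1]) matches <- matches + 1L
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2 || j == 1) {
      cand <- c(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                Iy[i - 1, j] - open - ext)
      state <- if (i > 2 || j > 1) which.max(cand) else 1
      i <- i - 1
    } else {
      cand <- c(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                Ix[i, j - 1] - open - ext)
      state <- c(1, 3, 2)[if (j > 2 || i > 1) which.max(cand) else 1]
      j <- j - 1
    }
  }
  list(score = score, identity = 100 * matches / cols, columns = cols)
}

# Smith-Waterman local score under a substitution matrix with affine gaps.
sw_oracle <- function(a, b, submat, open = 10, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[x[i - 1], y[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                      Iy[i - 1, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                      Ix[i, j - 1] - open - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Exhaustive edit comparison under the fuzzy-PBS contract: align prefixes of
# q and r, substitutions and internal indels counted, alignment may stop
# when either string is exhausted (the other's tail is free). Pareto search
# over indel usage; returns the decision and the best (subs, indels).
fuzzy_oracle <- function(q, r, max_total = 2, max_indels = 1) {
  x <- strsplit(q, "")[[1]]
  y <- strsplit(r, "")[[1]]
  n <- length(x); m <- length(y)
  INF <- 1e9
  # subs[i+1, j+1, k+1]: min substitutions aligning q[1..i], r[1..j], k indels
  subs <- array(INF, c(n + 1, m + 1, max_indels + 1))
  subs[1, 1, 1] <- 0
  for (i in 0:n) for (j in 0:m) for (k in 0:max_indels) {
    v <- subs[i + 1, j + 1, k + 1]
    if (v >= INF) next
    if (i < n && j < m) {
      cost <- v + (x[i + 1] != y[j + 1])
      if (cost < subs[i + 2, j + 2, k + 1]) subs[i + 2, j + 2, k + 1] <- cost
    }
    if (k < max_indels) {
      if (i < n && v < subs[i + 2, j + 1, k + 2]) subs[i + 2, j + 1, k + 2] <- v
      if (j < m && v < subs[i + 1, j + 2, k + 2]) subs[i + 1, j + 2, k + 2] <- v
    }
  }
  best <- NULL
  for (i in 0:n) for (j in 0:m) for (k in 0:max_indels) {
    if (i < n && j < m) next   # free tails only once a string is exhausted
    s <- subs[i + 1, j + 1, k + 1]
    if (s >= INF || s + k > max_total) next
    if (is.null(best) || s + k < best$subs + best$indels ||
        (s + k == best$subs + best$indels && k < best$indels))
      best <- list(subs = s, indels = k, aligned = min(i, j))
  }
  best
}

# dominant tandem period by raw autocorrelation of base agreement
autocorrelation_period <- function(dna, max_period = 200) {
  x <- strsplit(dna, "")[[1]]
  n <- length(x)
  agreement <- vapply(2:min(max_period, n - 1), function(p) {
    mean(x[seq_len(n - p)] == x[seq_len(n - p) + p])
  }, numeric(1))
  (2:min(max_period, n - 1))[which.max(agreement)]
}

# path-length (patristic) matrix of a newick tree, via ape
newick_path_lengths <- function(nwk) {
  tr <- ape::read.tree(text = nwk)
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_prot <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      n, TRUE), collapse = "")

# substitution-only mutant with k substitutions (avoiding given positions)
mutate_k <- function(s, k, protect = integer()) {
  x <- strsplit(s, "")[[1]]
  pos <- sample(setdiff(seq_along(x), protect), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

blosum62 <- function() ltrclass:::prot_matrix("BLOSUM62")

# protein mutant with k substitutions at random positions
mut_rand_prot <- function(p, k) {
  x <- strsplit(p, "")[[1]]
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pos <- sample(seq_along(x), k)
  for (i in pos) x[i] <- sample(setdiff(aas, x[i]), 1)
  paste(x, collapse = "")
}

# protein mutant with k substitutions at evenly spaced interior positions
# (deterministic, keeps local alignments full-length, so identity is
# exactly (n-k)/n — used for threshold-boundary fixtures)
mut_even_prot <- function(p, k) {
  x <- strsplit(p, "")[[1]]
  pos <- round(seq(3, length(x) - 2, length.out = k))
  for (i in pos) x[i] <- setdiff(c("A", "G", "V", "L", "S", "T"), x[i])[1]
  paste(x, collapse = "")
}

# additive distances of the tree ((A:1,B:2):1,(C:3,D:1)); NJ must recover
# both topology and branch lengths exactly
additive_matrix_4 <- function() {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  m["A", "B"] <- m["B", "A"] <- 3
  m["A", "C"] <- m["C", "A"] <- 5
  m["A", "D"] <- m["D", "A"] <- 3
  m["B", "C"] <- m["C", "B"] <- 6
  m["B", "D"] <- m["D", "B"] <- 4
  m["C", "D"] <- m["D", "C"] <- 4
  m
}
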