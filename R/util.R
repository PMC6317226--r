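# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

random_protein <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# overlap length of two 1-based closed intervals given as c(start, end)
interval_overlap <- function(a, b) {
  max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
}

# Minimal union-find for connected components; returns integer component ids
# (1..k, renumbered in order of first appearance).
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in edges) {
      ri <- find(e[1]); rj <- find(e[2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Run code with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-item sub-seed derived from a master seed (kept < 2^31).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}
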