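#' Concatenated core-domain protein of an element
#'
#' For redundancy reduction and phylogeny the PROT, RT, RH and INT domain
#' proteins of an element are concatenated in that fixed order (regardless
#' of their genomic order, which differs between superfamilies).
#'
#' @param element an annotated `ltr_element`.
#' @return Amino-acid string, or `NA_character_` (with a warning) when any
#'   of the four domains is missing.
#' @export
concat_domains <- function(element) {
  calls <- element$architecture$calls
  types <- c("PROT", "RT", "RH", "INT")
  parts <- character(length(types))
  for (i in seq_along(types)) {
    hit <- which(calls$domain_type == types[i])
    if (length(hit) != 1) {
      warning("element ", element$seq$id, " skipped: domain ", types[i],
              if (!length(hit)) " missing" else " duplicated")
      return(NA_character_)
    }
    parts[i] <- calls$qseq[hit]
  }
  paste(parts, collapse = "")
}

#' Cluster proteins by identity and coverage
#'
#' A pair of sequences is connected when their local alignment reaches at
#' least `min_identity` percent identity over at least `min_coverage`
#' percent of the shorter sequence; clusters are the connected components
#' of this graph.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param config an [pipeline_config()]; `cluster_min_identity` and
#'   `cluster_min_coverage` apply.
#' @return Integer cluster ids named by protein, numbered by first
#'   appearance.
#' @export
cluster_by_identity <- function(proteins, config = pipeline_config()) {
  n <- length(proteins)
  stopifnot(n >= 1)
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      al <- align_protein_local(proteins[[i]], proteins[(i + 1):n], config)
      shorter <- pmin(nchar(proteins[[i]]), nchar(proteins[(i + 1):n]))
      span <- pmin(al$qend - al$qstart + 1L, al$rend - al$rstart + 1L)
      hit <- al$identity >= config$cluster_min_identity &
        100 * span / shorter >= config$cluster_min_coverage
      for (j in which(hit)) edges[[length(edges) + 1L]] <- c(i, i + j)
    }
  }
  comp <- union_find_components(n, edges)
  stats::setNames(comp, names(proteins))
}

#' Select the representative sequence of a cluster
#'
#' Greedy incremental scheme in the CD-HIT style: members are sorted by
#' length (descending; ties by id), the first becomes a seed, and each
#' subsequent member joins the first seed it matches at or above the
#' identity threshold, else founds a new seed. The cluster representative
#' is the seed of the largest sub-group (ties: longest seed).
#'
#' @param members character vector of member ids.
#' @param proteins named character vector covering the members.
#' @param config an [pipeline_config()]; `rep_identity` (0--1 scale, the
#'   CD-HIT `-c` convention) applies.
#' @return The representative member id.
#' @export
select_representative <- function(members, proteins, config = pipeline_config()) {
  stopifnot(length(members) >= 1, all(members %in% names(proteins)))
  lens <- nchar(proteins[members])
  ord <- members[order(-lens, members)]
  seeds <- character()
  assign_to <- stats::setNames(character(length(ord)), ord)
  for (m in ord) {
    placed <- FALSE
    for (s in seeds) {
      al <- local_align(proteins[[m]], proteins[[s]], config)
      if (al$identity / 100 >= config$rep_identity) {
        assign_to[m] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, m)
      assign_to[m] <- m
    }
  }
  sizes <- table(assign_to)
  top <- max(sizes)
  cand <- names(sizes)[sizes == top]
  cand[order(-nchar(proteins[cand]), cand)][1]
}

#' Observed-distance matrix from a multiple alignment
#'
#' Pairwise observed distance (p-distance): one minus the fraction of
#' identical residues over columns where neither sequence has a gap.
#'
#' @param alignment named character vector of equal-length aligned rows
#'   (gaps as `-`).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
observed_distance_matrix <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 2)
  if (length(unique(nchar(alignment))) != 1)
    stop("ragged alignment: rows differ in length")
  rows <- lapply(alignment, chars)
  labs <- names(alignment) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- rows[[i]] != "-" & rows[[j]] != "-"
      if (!any(ok)) stop("no comparable columns between rows ", i, " and ", j)
      d[i, j] <- d[j, i] <- 1 - mean(rows[[i]][ok] == rows[[j]][ok])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Classic agglomerative neighbor joining on a distance matrix, returning
#' an unrooted tree in newick format. Negative branch lengths (possible on
#' non-additive input) are clamped to zero with the deficit transferred to
#' the sister branch, preserving the path length between the joined pair.
#'
#' @param d symmetric distance matrix with labeled rows (n >= 3).
#' @return Newick string (with branch lengths, terminated by `;`).
#' @export
nj_tree <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 3) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isSymmetric(unname(d)))
  labs <- rownames(d) %||% as.character(seq_len(n))
  nodes <- labs
  D <- unname(d)
  clamp <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    l <- clamp(li, lj)
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(l[1]), nodes[j], fmt(l[2]))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(ls[1]),
          nodes[2], fmt(ls[2]), nodes[3], fmt(ls[3]))
}
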