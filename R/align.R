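#' Global DNA alignment identity
#'
#' Aligns two DNA strings globally (Needleman-Wunsch, match +1, mismatch -1,
#' affine gaps open -4 / extend -1 by default) and reports percent identity as
#' matches over alignment columns (gap columns included in the denominator).
#' This is the statistic the 5'/3' LTR similarity screen is applied to.
#'
#' @param a,b DNA strings.
#' @param config an [pipeline_config()] object supplying the scoring scheme.
#' @return A list with `identity` (percent), `score`, and `columns`.
#' @export
align_dna_global <- function(a, b, config = pipeline_config()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  key <- paste0("dna_", config$dna_match, "_", config$dna_mismatch)
  mat <- .matrix_cache[[key]]
  if (is.null(mat)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = config$dna_match, mismatch = config$dna_mismatch, baseOnly = FALSE)
    .matrix_cache[[key]] <- mat
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat,
    gapOpening = config$dna_gap_open, gapExtension = config$dna_gap_extend)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  list(identity = 100 * Biostrings::nmatch(pa) / cols,
       score = Biostrings::score(pa),
       columns = cols)
}

#' Percent identity between two LTR copies
#'
#' @inheritParams align_dna_global
#' @return Percent identity (0--100) over global alignment columns.
#' @examples
#' ltr_similarity("ACGTACGT", "ACGTACGT")  # 100
#' @export
ltr_similarity <- function(a, b, config = pipeline_config()) {
  align_dna_global(a, b, config)$identity
}

# Local protein alignment of one query segment against a set of reference
# proteins (vectorized over the references). Returns a data.frame with one row
# per reference: score, identity (percent over alignment columns), query and
# reference intervals (1-based closed, query coordinates within `query`), and
# the gap-free aligned query substring.
.matrix_cache <- new.env(parent = emptyenv())

# resolve a substitution matrix name to the actual matrix once per session
prot_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  m <- .matrix_cache[[name]]
  if (is.null(m)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    .matrix_cache[[name]] <- m
  }
  m
}

align_protein_local <- function(query, refs, config = pipeline_config(),
                                min_score = NULL) {
  stopifnot(length(refs) >= 1)
  nms <- if (is.null(names(refs))) as.character(seq_along(refs)) else names(refs)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(refs), Biostrings::AAString(query), type = "local",
    substitutionMatrix = prot_matrix(config$prot_matrix),
    gapOpening = config$prot_gap_open, gapExtension = config$prot_gap_extend)
  sc <- Biostrings::score(pa)
  keep <- seq_along(sc)
  if (!is.null(min_score)) {
    keep <- which(sc >= min_score)   # skip costly extraction for non-hits
    if (!length(keep)) {
      return(data.frame(ref = character(), score = numeric(),
                        identity = numeric(), qstart = integer(),
                        qend = integer(), rstart = integer(), rend = integer(),
                        qseq = character(), stringsAsFactors = FALSE))
    }
    pa <- pa[keep]
  }
  patt <- Biostrings::pattern(pa)   # reference side
  subj <- Biostrings::subject(pa)   # query side
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cols <- nchar(ap)
  matches <- mapply(function(a, b) {
    x <- strsplit(a, "", fixed = TRUE)[[1]]
    y <- strsplit(b, "", fixed = TRUE)[[1]]
    sum(x == y & x != "-")
  }, ap, as_, USE.NAMES = FALSE)
  data.frame(
    ref = nms[keep],
    score = sc[keep],
    identity = ifelse(cols > 0, 100 * matches / cols, 0),
    qstart = Biostrings::start(subj), qend = Biostrings::end(subj),
    rstart = Biostrings::start(patt), rend = Biostrings::end(patt),
    qseq = gsub("-", "", as_, fixed = TRUE),
    stringsAsFactors = FALSE)
}

#' Local protein alignment against one reference
#'
#' Smith-Waterman alignment (BLOSUM62, affine gaps open -10 / extend -1 by
#' default) of a translated query against a reference protein.
#'
#' @param query,ref amino-acid strings.
#' @param config an [pipeline_config()] object supplying the scoring scheme.
#' @return A one-row data.frame with score, identity and aligned intervals.
#' @export
local_align <- function(query, ref, config = pipeline_config()) {
  if (!nzchar(query) || !nzchar(ref)) stop("cannot align empty sequences")
  align_protein_local(query, stats::setNames(ref, "ref"), config)
}

# Edit comparison of two strings under the fuzzy-PBS budget: substitutions
# plus indels <= max_total, indels <= max_indels. Exhaustive over the allowed
# indel placements (the indel budget is <= 1 in practice, so enumeration is
# exact and cheap). Trailing bases pushed past the window end by an indel are
# not counted. Returns list(diffs = substitutions, indels, aligned_len) for
# the best decomposition within budget, or NULL.
constrained_edit <- function(q, r, max_total = 2, max_indels = 1) {
  best <- NULL
  consider <- function(subs, indels, len) {
    if (subs + indels > max_total || indels > max_indels) return()
    if (is.null(best) || subs + indels < best$diffs + best$indels ||
        (subs + indels == best$diffs + best$indels && indels < best$indels)) {
      best <<- list(diffs = as.integer(subs), indels = as.integer(indels),
                    aligned_len = as.integer(len))
    }
  }
  prefix_subs <- function(x, y) {
    m <- min(nchar(x), nchar(y))
    sum(chars(substr(x, 1, m)) != chars(substr(y, 1, m)))
  }
  if (nchar(q) == nchar(r)) consider(prefix_subs(q, r), 0L, nchar(q))
  if (max_indels >= 1) {
    qc <- chars(q); rc <- chars(r)
    if (length(qc) >= 2) {
      for (i in seq_along(qc)) {        # one base of q unmatched (insertion)
        qd <- paste(qc[-i], collapse = "")
        consider(prefix_subs(qd, r), 1L, min(nchar(qd), nchar(r)))
      }
    }
    if (length(rc) >= 2) {
      for (j in seq_along(rc)) {        # one base of r unmatched (deletion)
        rd <- paste(rc[-j], collapse = "")
        consider(prefix_subs(q, rd), 1L, min(nchar(q), nchar(rd)))
      }
    }
  }
  best
}
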