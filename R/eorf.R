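#' Find open reading frames
#'
#' Reports, for both strands and all three frames, every maximal stop-free
#' stretch starting at the first ATG after the preceding stop (or sequence
#' start) and running to the next stop (or sequence end), with at least
#' `min_codons` codons (the stop codon is not counted). Coordinates are on
#' the forward strand, 1-based inclusive, excluding the stop codon.
#'
#' @param dna DNA string.
#' @param min_codons minimum ORF length in codons.
#' @param require_atg must the ORF start at ATG? (default TRUE).
#' @return data.frame with `start`, `end`, `strand`, `codons`.
#' @export
find_orfs <- function(dna, min_codons = 250, require_atg = TRUE) {
  n <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (f in 1:3) {
      ncod <- (nchar(s) - f + 1L) %/% 3L
      if (ncod < 1) next
      starts <- f + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      stop_idx <- which(codons %in% STOP_CODONS)
      bounds <- c(0L, stop_idx, ncod + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        lo <- bounds[b] + 1L; hi <- bounds[b + 1L] - 1L
        if (hi - lo + 1L < min_codons) next
        if (require_atg) {
          atg <- which(codons[lo:hi] == "ATG")
          if (!length(atg)) next
          lo <- lo + atg[1] - 1L
        }
        ncodons <- hi - lo + 1L
        if (ncodons < min_codons) next
        a <- starts[lo]; b2 <- starts[hi] + 2L
        iv <- if (strand == "+") c(a, b2) else c(n - b2 + 1L, n - a + 1L)
        out[[length(out) + 1L]] <- data.frame(
          start = iv[1], end = iv[2], strand = strand, codons = ncodons,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), codons = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Label an extra ORF by position and orientation
#'
#' ORFs overlapping the polyprotein coding region are not extra ORFs and are
#' discarded (label NA). The rest are labeled 5' or 3' by their position
#' relative to the polyprotein, with suffix F when on the polyprotein strand
#' and R otherwise: `eORF-5'F`, `eORF-5'R`, `eORF-3'F`, `eORF-3'R`.
#'
#' @param orf one-row data.frame (or list) with `start`, `end`, `strand`.
#' @param polyprotein_interval c(start, end) spanning the first to last
#'   domain call.
#' @param polyprotein_strand strand of the polyprotein (default "+").
#' @return The label string, or `NA_character_` for discarded ORFs.
#' @export
label_eorf <- function(orf, polyprotein_interval, polyprotein_strand = "+") {
  if (is.null(polyprotein_interval) || anyNA(polyprotein_interval))
    stop("cannot label eORFs: polyprotein interval unknown")
  if (interval_overlap(c(orf$start, orf$end), polyprotein_interval) > 0)
    return(NA_character_)
  side <- if (orf$end < polyprotein_interval[1]) "5'" else "3'"
  orient <- if (orf$strand == polyprotein_strand) "F" else "R"
  paste0("eORF-", side, orient)
}

#' Detect tandem repeat arrays
#'
#' Scans every candidate period up to `tandem_max_period` by comparing the
#' sequence against itself at that lag, collecting maximal segments whose
#' base-level agreement is at least `tandem_min_agreement` (score +1 match,
#' -4 mismatch, so segments break even exactly at 80% agreement).
#' Overlapping arrays found at different periods are resolved keeping the
#' higher copy number. Only arrays with at least `tandem_min_monomers`
#' copies spanning more than `tandem_min_span` bp are reported.
#'
#' @param dna DNA string.
#' @param config an [pipeline_config()].
#' @return data.frame with `start`, `end`, `period`, `copies`, `consensus`.
#' @export
find_tandem_arrays <- function(dna, config = pipeline_config()) {
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copies = numeric(), consensus = character(),
                      stringsAsFactors = FALSE)
  n <- nchar(dna)
  if (n < config$tandem_min_span) return(empty)
  x <- chars(dna)
  mis_pen <- config$tandem_min_agreement / (1 - config$tandem_min_agreement)
  cands <- list()
  periods <- candidate_periods(dna, min(config$tandem_max_period, n %/% 2L))
  for (p in periods) {
    m <- x[seq_len(n - p)] == x[seq_len(n - p) + p]
    sc <- ifelse(m, 1, -mis_pen)
    min_region <- max(config$tandem_min_span - p,
                      (config$tandem_min_monomers - 1) * p)
    segs <- positive_segments(sc, min_region)
    for (sg in segs) {
      a <- sg[1]; b <- sg[2] + p
      span <- b - a + 1L
      copies <- span / p
      if (copies >= config$tandem_min_monomers && span > config$tandem_min_span) {
        cands[[length(cands) + 1L]] <- data.frame(
          start = a, end = b, period = p, copies = copies,
          consensus = substr(dna, a, a + p - 1L), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cands)) return(empty)
  arr <- do.call(rbind, cands)
  arr <- arr[order(-arr$copies, arr$period), , drop = FALSE]
  keep <- logical(nrow(arr))
  for (i in seq_len(nrow(arr))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (interval_overlap(c(arr$start[i], arr$end[i]),
                           c(arr$start[j], arr$end[j])) > 0) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  arr <- arr[keep, , drop = FALSE]
  arr[order(arr$start), , drop = FALSE]
}

# candidate tandem periods from spaced k-mer self-matches: any array with
# >= 80% monomer agreement over > 150 bp necessarily repeats exact 8-mers at
# a lag equal to its period, so the distinct spacings between repeated 8-mer
# occurrences enumerate the periods worth scoring
candidate_periods <- function(dna, max_period, k = 8L) {
  n <- nchar(dna)
  if (n < k + 2L || max_period < 2L) return(integer())
  st <- seq_len(n - k + 1L)
  km <- substring(dna, st, st + k - 1L)
  pos <- split(st, km)
  pos <- pos[lengths(pos) > 1L]
  if (!length(pos)) return(integer())
  d <- unlist(lapply(pos, function(p) diff(p)), use.names = FALSE)
  sort(unique(d[d >= 2L & d <= max_period]))
}

# maximal positive-scoring segments of a score vector (restart scan, i.e.
# cur_i = max(cur_{i-1} + sc_i, 0), vectorized as S_i - min(S_0..S_i));
# returns list of c(start, end) index pairs where end is the last running
# maximum of the segment
positive_segments <- function(sc, min_len = 1L) {
  S <- cumsum(sc)
  pref <- cummin(c(0, S))          # pref[i+1] = min(S_0..S_i)
  cur <- S - pref[-1]
  pos <- cur > 1e-9
  if (!any(pos)) return(list())
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values & r$lengths >= min_len)) {
    a <- starts[k]; b <- ends[k]
    seg_cur <- cur[a:b]
    best_end <- a + max(which(seg_cur >= max(seg_cur) - 1e-9)) - 1L
    segs[[length(segs) + 1L]] <- c(a, best_end)
  }
  segs
}

#' Exclude extra ORFs arising from tandem repeats
#'
#' Low-complexity tandem arrays often lack stop codons, so ORFs over such
#' regions are artifacts. An eORF overlapping a qualifying array by at least
#' half of its own length is marked excluded (reason `tandem_repeat`).
#'
#' @param orfs data.frame of labeled ORFs (`start`, `end`, ...).
#' @param arrays data.frame from [find_tandem_arrays()] on the same element.
#' @return `orfs` with logical `excluded` and character `reason` columns.
#' @export
filter_eorfs <- function(orfs, arrays) {
  orfs$excluded <- logical(nrow(orfs))
  orfs$reason <- rep(NA_character_, nrow(orfs))
  if (!nrow(orfs) || is.null(arrays) || !nrow(arrays)) return(orfs)
  for (i in seq_len(nrow(orfs))) {
    len <- orfs$end[i] - orfs$start[i] + 1L
    for (j in seq_len(nrow(arrays))) {
      ov <- interval_overlap(c(orfs$start[i], orfs$end[i]),
                             c(arrays$start[j], arrays$end[j]))
      if (ov >= 0.5 * len) {
        orfs$excluded[i] <- TRUE
        orfs$reason[i] <- "tandem_repeat"
        break
      }
    }
  }
  orfs
}

#' Group eORF proteins by mutual similarity
#'
#' All-versus-all local alignment; a pair is connected when its
#' Karlin-Altschul E-value (ungapped BLOSUM62 constants lambda = 0.3176,
#' K = 0.134; search space = product of the pair's lengths times the number
#' of pairs) is below the threshold. Groups are the connected components;
#' singletons are groups of one.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param evalue_threshold significance threshold (default the config's
#'   `eorf_group_evalue`, 1e-10).
#' @param config an [pipeline_config()].
#' @return Integer vector of group ids (named by protein), numbered in order
#'   of first appearance.
#' @export
group_eorf_proteins <- function(proteins,
                                evalue_threshold = NULL,
                                config = pipeline_config()) {
  if (is.null(evalue_threshold)) evalue_threshold <- config$eorf_group_evalue
  n <- length(proteins)
  if (!n) return(stats::setNames(integer(), character()))
  npairs <- n * (n - 1) / 2
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      al <- align_protein_local(proteins[[i]],
                                proteins[(i + 1):n], config)
      ev <- config$ka_k * nchar(proteins[[i]]) *
        nchar(proteins[(i + 1):n]) * npairs * exp(-config$ka_lambda * al$score)
      for (j in which(ev < evalue_threshold)) {
        edges[[length(edges) + 1L]] <- c(i, i + j)
      }
    }
  }
  comp <- union_find_components(n, edges)
  stats::setNames(comp, names(proteins))
}
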