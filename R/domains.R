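#' Six-frame translation
#'
#' Translates a DNA string in all six reading frames under the standard
#' genetic code. Stops are `*`; any codon containing an ambiguous base is
#' translated as `X`. Frames -1..-3 translate the reverse complement.
#'
#' @param dna DNA string over A,C,G,T,N.
#' @return Named character vector of six translations
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @examples
#' six_frame_translate("ATGGCC")[["+1"]]  # "MA"
#' @export
six_frame_translate <- function(dna) {
  fwd <- toupper(dna)
  rev <- revcomp(fwd)
  tr <- function(s, f) {
    ncod <- (nchar(s) - f + 1L) %/% 3L
    if (ncod < 1L) return("")
    starts <- f + 3L * (seq_len(ncod) - 1L)
    aa <- unname(AA_BY_CODON[substring(s, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"   # codons containing N (or other ambiguity)
    paste(aa, collapse = "")
  }
  c("+1" = tr(fwd, 1L), "+2" = tr(fwd, 2L), "+3" = tr(fwd, 3L),
    "-1" = tr(rev, 1L), "-2" = tr(rev, 2L), "-3" = tr(rev, 3L))
}

AA_BY_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
})

# Split a frame translation at stop codons into segments of >= min_aa
# residues. Returns data.frame(aa_start, aa_end, seq) in translation
# coordinates (1-based).
translation_segments <- function(trans, min_aa = 20) {
  if (!nzchar(trans)) {
    return(data.frame(aa_start = integer(), aa_end = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trans, "*", fixed = TRUE)[[1]]
  starts <- integer(length(parts))
  pos <- 1L
  for (i in seq_along(parts)) {
    starts[i] <- pos
    pos <- pos + nchar(parts[i]) + 1L
  }
  keep <- nchar(parts) >= min_aa
  data.frame(aa_start = starts[keep],
             aa_end = starts[keep] + nchar(parts[keep]) - 1L,
             seq = parts[keep], stringsAsFactors = FALSE)
}

# Map an amino-acid interval of a frame translation to forward-strand DNA
# coordinates. frame in {1,2,3,-1,-2,-3}; n = DNA length.
aa_to_dna <- function(aa_start, aa_end, frame, n) {
  f <- abs(frame)
  a <- f + 3L * (aa_start - 1L)
  b <- f + 3L * aa_end - 1L
  if (frame > 0) c(a, b) else c(n - b + 1L, n - a + 1L)
}

# 4-mer prefilter index of the reference proteins (built lazily, cached on
# the refdb's environment).
refdb_kmer_index <- function(refdb, k = 4L) {
  env <- refdb$index
  if (!is.null(env$kmer)) return(env$kmer)
  kmers <- lapply(refdb$proteins, function(p) {
    if (nchar(p) < k) return(character())
    st <- seq_len(nchar(p) - k + 1L)
    unique(substring(p, st, st + k - 1L))
  })
  idx <- split(rep(seq_along(kmers), lengths(kmers)), unlist(kmers))
  env$kmer <- idx
  idx
}

#' Translated search of an element against the reference domain database
#'
#' Each of the six frame translations is segmented at stop codons; segments
#' of at least `scan_min_segment_aa` residues are aligned locally
#' (Smith-Waterman, BLOSUM62) against reference entries sharing at least
#' `scan_min_kmer_hits` distinct 4-mers with the segment (an exact-word
#' prefilter in the BLAST tradition; lower it to 1 for very distant
#' references). Hits above the score and identity thresholds are returned
#' with their DNA coordinates mapped back (frame-aware).
#'
#' @param seq an `ltr_seq` record or DNA string.
#' @param refdb an `ltr_refdb`.
#' @param config an [pipeline_config()]; thresholds `scan_min_score` and
#'   `scan_min_identity` apply.
#' @return A data.frame of protein hits (possibly 0 rows): `ref_entry`,
#'   `domain_type`, `lineage`, `superfamily`, `start`, `end`, `strand`,
#'   `frame`, `score`, `identity`, `rstart`, `rend`, `qseq` (gap-free aligned
#'   element protein).
#' @export
scan_domains <- function(seq, refdb, config = pipeline_config()) {
  s <- if (inherits(seq, "ltr_seq")) seq$residues else seq
  n <- nchar(s)
  stopifnot(nrow(refdb$entries) >= 1)
  idx <- refdb_kmer_index(refdb)
  frames <- six_frame_translate(s)
  frame_num <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out <- list()
  for (fi in seq_along(frames)) {
    segs <- translation_segments(frames[[fi]], config$scan_min_segment_aa)
    for (si in seq_len(nrow(segs))) {
      seg <- segs$seq[si]
      st <- seq_len(nchar(seg) - 3L)
      ids <- unlist(idx[unique(substring(seg, st, st + 3L))], use.names = FALSE)
      if (!length(ids)) next
      shared <- tabulate(ids, nbins = length(refdb$proteins))
      cand <- which(shared >= config$scan_min_kmer_hits)
      if (!length(cand)) next
      # keep the strongest word-sharing references per domain type for
      # scoring; the best reference dominates all downstream uses
      ctypes <- refdb$entries$domain_type[cand]
      cand <- unlist(lapply(split(cand, ctypes), function(cc) {
        cc[order(-shared[cc])][seq_len(min(length(cc), config$scan_max_refs_per_type))]
      }), use.names = FALSE)
      # phase 1: scores only (cheap); phase 2: full alignment of the best
      # reference per domain type among the survivors
      sc <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(refdb$proteins[cand]),
        Biostrings::AAString(seg), type = "local",
        substitutionMatrix = prot_matrix(config$prot_matrix),
        gapOpening = config$prot_gap_open,
        gapExtension = config$prot_gap_extend, scoreOnly = TRUE)
      surv <- cand[sc >= config$scan_min_score]
      if (!length(surv)) next
      surv_sc <- sc[sc >= config$scan_min_score]
      types <- refdb$entries$domain_type[surv]
      best_per_type <- vapply(split(seq_along(surv), types),
                              function(ii) surv[ii[which.max(surv_sc[ii])]],
                              integer(1))
      al <- align_protein_local(seg, refdb$proteins[best_per_type], config,
                                min_score = config$scan_min_score)
      if (!nrow(al)) next
      keep <- al$identity >= config$scan_min_identity
      if (!any(keep)) next
      al <- al[keep, , drop = FALSE]
      ent <- refdb$entries[match(al$ref, refdb$entries$name), ]
      dna <- t(vapply(seq_len(nrow(al)), function(i) {
        aa_to_dna(segs$aa_start[si] + al$qstart[i] - 1L,
                  segs$aa_start[si] + al$qend[i] - 1L,
                  frame_num[fi], n)
      }, integer(2)))
      out[[length(out) + 1L]] <- data.frame(
        ref_entry = al$ref, domain_type = ent$domain_type,
        lineage = ent$lineage, superfamily = ent$superfamily,
        start = dna[, 1], end = dna[, 2],
        strand = if (frame_num[fi] > 0) "+" else "-",
        frame = frame_num[fi], score = al$score, identity = al$identity,
        rstart = al$rstart, rend = al$rend, qseq = al$qseq,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(ref_entry = character(), domain_type = character(),
                      lineage = character(), superfamily = character(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), score = numeric(), identity = numeric(),
                      rstart = integer(), rend = integer(), qseq = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, -res$score), , drop = FALSE]
}

#' Chain frameshift-split hits into domain calls
#'
#' Same-domain-type, same-strand hits that are colinear (both DNA and
#' reference coordinates increasing) with a DNA gap of at most `max_gap` are
#' merged into a single call; this recovers domains whose coding region
#' carries frameshift mutations, which surface as adjacent hits in different
#' frames. Overlapping calls of different types are then resolved keeping
#' the higher score (a call is dropped when more than half of the shorter
#' interval overlaps a better call).
#'
#' @param hits data.frame from [scan_domains()].
#' @param config an [pipeline_config()]; `chain_max_gap` applies.
#' @return A data.frame of domain calls: `domain_type`, `start`, `end`,
#'   `strand`, `best_ref`, `lineage`, `superfamily`, `score`, `identity`,
#'   `support`, `qseq`.
#' @export
chain_hits <- function(hits, config = pipeline_config()) {
  empty <- data.frame(domain_type = character(), start = integer(),
                      end = integer(), strand = character(),
                      best_ref = character(), lineage = character(),
                      superfamily = character(), score = numeric(),
                      identity = numeric(), support = integer(),
                      qseq = character(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  # keep only the best reference per (type, strand, locus) before chaining:
  # hits of one domain against many references all describe one locus, so
  # chain over the per-locus best hits
  calls <- list()
  for (key in unique(paste(hits$domain_type, hits$strand))) {
    h <- hits[paste(hits$domain_type, hits$strand) == key, , drop = FALSE]
    h <- resolve_same_type(h)
    h <- h[order(h$start), , drop = FALSE]
    i <- 1L
    while (i <= nrow(h)) {
      members <- h[i, , drop = FALSE]
      j <- i + 1L
      while (j <= nrow(h)) {
        last <- members[nrow(members), ]
        gap <- h$start[j] - last$end - 1L
        colinear <- h$start[j] > last$start & h$rstart[j] >= last$rstart
        if (gap <= config$chain_max_gap && colinear && gap > -30) {
          members <- rbind(members, h[j, ])
          j <- j + 1L
        } else break
      }
      best <- members[which.max(members$score), ]
      ord <- order(members$rstart)
      calls[[length(calls) + 1L]] <- data.frame(
        domain_type = best$domain_type,
        start = min(members$start), end = max(members$end),
        strand = best$strand, best_ref = best$ref_entry,
        lineage = best$lineage, superfamily = best$superfamily,
        score = sum(members$score), identity = best$identity,
        support = nrow(members),
        qseq = paste(members$qseq[ord], collapse = ""),
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  calls <- do.call(rbind, calls)
  # cross-type dominance: drop a call when most of it lies under a better one
  calls <- calls[order(-calls$score), , drop = FALSE]
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- interval_overlap(c(calls$start[i], calls$end[i]),
                             c(calls$start[j], calls$end[j]))
      shorter <- min(calls$end[i] - calls$start[i] + 1L,
                     calls$end[j] - calls$start[j] + 1L)
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  calls <- calls[keep, , drop = FALSE]
  calls[order(calls$start), , drop = FALSE]
}

# Among same-type hits, collapse stacks of overlapping hits (same locus,
# different references) to the best-scoring one.
resolve_same_type <- function(h) {
  h <- h[order(-h$score), , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- interval_overlap(c(h$start[i], h$end[i]), c(h$start[j], h$end[j]))
      shorter <- min(h$end[i] - h$start[i] + 1L, h$end[j] - h$start[j] + 1L)
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  h[keep, , drop = FALSE]
}

#' Validate the domain architecture of an element
#'
#' Checks the ordered domain calls against the two superfamily templates:
#' Ty1/copia elements carry (GAG-)PROT-INT-RT-RH, Ty3/gypsy elements
#' (GAG-)PROT-RT-RH-INT. GAG is optional (it is often too diverged to
#' detect) and is recorded as `missing_GAG` rather than rejected. Flags:
#' `bad_order` when neither template matches, `duplicate_domain` when any
#' type is called twice, `chimera` when the best-hit superfamily tokens of
#' the core domains disagree. For Tat-lineage elements the position of the
#' additional ribonuclease H (aRH) relative to its neighbors is recorded
#' (`PROT_RT`, `RH_INT`, or `after_INT`).
#'
#' @param calls data.frame from [chain_hits()].
#' @return A list of class `domain_architecture`: `calls`, `superfamily`
#'   (`Ty1/copia`, `Ty3/gypsy` or `undetermined`), `arh_position`,
#'   `chromodomain` (`CHD`, `CHDCR` or `none`) and `flags`.
#' @export
validate_architecture <- function(calls) {
  arch <- function(superfamily, arh, chd, flags) {
    structure(list(calls = calls, superfamily = superfamily,
                   arh_position = arh, chromodomain = chd, flags = flags),
              class = "domain_architecture")
  }
  if (is.null(calls) || !nrow(calls))
    return(arch("undetermined", "none", "none", "no_polyprotein"))
  calls <- calls[order(calls$start), , drop = FALSE]
  flags <- character()
  if (anyDuplicated(calls$domain_type))
    flags <- c(flags, "duplicate_domain")
  core_types <- c("GAG", "PROT", "INT", "RT", "RH")
  core <- calls$domain_type[calls$domain_type %in% core_types]
  matches_template <- function(template) {
    identical(core, template) || identical(core, template[-1])
  }
  superfamily <- "undetermined"
  if (matches_template(c("GAG", "PROT", "INT", "RT", "RH"))) {
    superfamily <- "Ty1/copia"
  } else if (matches_template(c("GAG", "PROT", "RT", "RH", "INT"))) {
    superfamily <- "Ty3/gypsy"
  } else {
    flags <- c(flags, "bad_order")
  }
  if (superfamily != "undetermined" && !"GAG" %in% core)
    flags <- c(flags, "missing_GAG")
  vote_types <- c("PROT", "INT", "RT", "RH")
  sf_tokens <- unique(calls$superfamily[calls$domain_type %in% vote_types])
  if (length(sf_tokens) > 1) flags <- c(flags, "chimera")
  arh_position <- "none"
  ai <- which(calls$domain_type == "aRH")
  if (length(ai)) {
    ai <- ai[1]
    before <- calls$domain_type[seq_len(ai - 1L)]
    after <- calls$domain_type[-seq_len(ai)]
    before <- before[before %in% core_types]
    after <- after[after %in% core_types]
    prev <- if (length(before)) before[length(before)] else NA
    nxt <- if (length(after)) after[1] else NA
    arh_position <- if (identical(prev, "PROT") && identical(nxt, "RT")) "PROT_RT"
      else if (identical(prev, "RH") && identical(nxt, "INT")) "RH_INT"
      else if (identical(prev, "INT")) "after_INT"
      else "other"
  }
  chd <- if ("CHDCR" %in% calls$domain_type) "CHDCR"
    else if ("CHD" %in% calls$domain_type) "CHD" else "none"
  arch(superfamily, arh_position, chd, flags)
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("<domain_architecture> %s  order: %s\n", x$superfamily,
              paste(x$calls$domain_type, collapse = "-")))
  if (x$arh_position != "none") cat("  aRH position:", x$arh_position, "\n")
  if (x$chromodomain != "none") cat("  chromodomain:", x$chromodomain, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
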