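#' Prepare a tRNA library for PBS detection
#'
#' Mature tRNAs carry a 3' CCA that is added post-transcriptionally and is
#' therefore absent from genomically predicted sequences; this appends a
#' single terminal CCA to every entry that lacks one (idempotent).
#'
#' @param trnas a `trna_library`.
#' @return The library with every entry ending in exactly one CCA.
#' @export
prepare_trnas <- function(trnas) {
  needs <- !endsWith(trnas$residues, "CCA")
  trnas$residues[needs] <- paste0(trnas$residues[needs], "CCA")
  trnas
}

pbs_window_seq <- function(element, config) {
  if (is.null(element$ltr)) stop("PBS requires 5' LTR")
  s <- element$seq$residues
  from <- element$ltr$five[2] + 1L
  substr(s, from, min(nchar(s), from + config$pbs_window - 1L))
}

new_primer_call <- function(mode, trna_id = NULL, isoacceptor = NULL,
                            match_len = NA_integer_, diffs = 0L, indels = 0L,
                            start = NA_integer_, end = NA_integer_,
                            offset = NA_integer_) {
  structure(list(mode = mode, trna_id = trna_id, isoacceptor = isoacceptor,
                 match_len = match_len, diffs = diffs, indels = indels,
                 start = start, end = end, offset = offset),
            class = "primer_call")
}

#' @export
print.primer_call <- function(x, ...) {
  cat(sprintf("<primer_call> %s", x$mode))
  if (!is.null(x$trna_id)) cat(sprintf(" (%s, %d bp", x$isoacceptor, x$match_len))
  else if (!is.na(x$match_len)) cat(sprintf(" (%d bp", x$match_len))
  if (!is.null(x$trna_id) || !is.na(x$match_len)) {
    if (x$diffs + x$indels > 0)
      cat(sprintf(", %d subs + %d indels", x$diffs, x$indels))
    cat(")")
  }
  cat("\n")
  invisible(x)
}

#' Exact full-tRNA primer binding site
#'
#' Searches the window immediately downstream of the 5' LTR for the longest
#' exact match to the reverse complement of a 3'-terminal suffix of any
#' tRNA (the suffix must include the tRNA's final base). A call requires at
#' least `pbs_min_exact` matched bases. Ties are broken by smaller offset
#' from the LTR, then tRNA id.
#'
#' @param element an `ltr_element` with a located 5' LTR.
#' @param trnas a prepared `trna_library` (see [prepare_trnas()]).
#' @param config an [pipeline_config()].
#' @return A `primer_call` of mode `full_tRNA`, or `NULL`.
#' @export
find_exact_pbs <- function(element, trnas, config = pipeline_config()) {
  win <- pbs_window_seq(element, config)
  minm <- config$pbs_min_exact
  if (nchar(win) < minm) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(trnas))) {
    t <- trnas$residues[i]
    nt <- nchar(t)
    anchor <- revcomp(substr(t, nt - minm + 1L, nt))
    hits <- gregexpr(anchor, win, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (pos in as.integer(hits)) {
      m <- minm
      while (m < min(nt, nchar(win) - pos + 1L)) {
        nxt <- substr(win, pos + m, pos + m)
        if (nxt != complement_base(substr(t, nt - m, nt - m))) break
        m <- m + 1L
      }
      cand <- list(m = m, pos = pos, id = trnas$id[i], iso = trnas$isoacceptor[i])
      if (is.null(best) || cand$m > best$m ||
          (cand$m == best$m && (cand$pos < best$pos ||
           (cand$pos == best$pos && cand$id < best$id)))) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  from <- element$ltr$five[2] + best$pos
  new_primer_call("full_tRNA", best$id, best$iso, best$m,
                  start = from, end = from + best$m - 1L,
                  offset = best$pos - 1L)
}

#' Half-molecule tRNA primer binding site
#'
#' Some elements are primed by the 5' half of a tRNA cleaved in the
#' anticodon stem. This searches the PBS window for exact matches to the
#' reverse complement of tRNA subsequences ending within a cleavage window
#' around the anticodon (anticodon start -3 .. +5). Post-transcriptionally
#' edited positions (e.g. the inosine of tRNA-Ile in Bianca elements, which
#' pairs with A, U and C) match any of their annotated pairing bases.
#'
#' @inheritParams find_exact_pbs
#' @return A `primer_call` of mode `half_tRNA`, or `NULL`. tRNAs lacking
#'   anticodon metadata are skipped with a warning.
#' @export
find_half_trna_pbs <- function(element, trnas, config = pipeline_config()) {
  win <- pbs_window_seq(element, config)
  minm <- config$pbs_min_exact
  if (nchar(win) < minm) return(NULL)
  wc <- chars(win)
  best <- NULL
  for (i in seq_len(nrow(trnas))) {
    ac <- trnas$anticodon_start[i]
    if (is.na(ac)) {
      warning("tRNA ", trnas$id[i], " lacks anticodon metadata; skipped")
      next
    }
    t <- chars(trnas$residues[i])
    ed <- trnas$edited[[i]]
    for (e in seq.int(max(minm, ac - 3L), min(length(t), ac + 5L))) {
      # pattern position k pairs with tRNA position e-k+1
      klen <- min(e, nchar(win))
      allowed <- lapply(seq_len(klen), function(k) {
        tp <- e - k + 1L
        if (nrow(ed) && tp %in% ed$index) chars(ed$allowed[match(tp, ed$index)])
        else complement_base(t[tp])
      })
      for (pos in seq_len(nchar(win) - minm + 1L)) {
        m <- 0L
        while (m < klen && pos + m <= nchar(win) &&
               wc[pos + m] %in% allowed[[m + 1L]]) m <- m + 1L
        if (m < minm) next
        cand <- list(m = m, pos = pos, id = trnas$id[i],
                     iso = trnas$isoacceptor[i], e = e)
        if (is.null(best) || cand$m > best$m ||
            (cand$m == best$m && (cand$pos < best$pos ||
             (cand$pos == best$pos && cand$id < best$id)))) best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  from <- element$ltr$five[2] + best$pos
  new_primer_call("half_tRNA", best$id, best$iso, best$m,
                  start = from, end = from + best$m - 1L,
                  offset = best$pos - 1L)
}

#' Fuzzy tRNA primer binding site
#'
#' For elements without an exact PBS but with a TGG (the reverse complement
#' of the universal 3' CCA) starting 0--5 bp downstream of the 5' LTR, the
#' 18 bp starting at that TGG are compared against the reverse complement
#' of each tRNA's 3'-terminal 18 bp under an edit budget of at most two
#' differences, at most one of which may be an indel.
#'
#' @inheritParams find_exact_pbs
#' @return A `primer_call` of mode `fuzzy_tRNA` with `diffs` (substitutions)
#'   and `indels` counts, or `NULL`.
#' @export
find_fuzzy_pbs <- function(element, trnas, config = pipeline_config()) {
  win <- pbs_window_seq(element, config)
  w <- config$fuzzy_window
  best <- NULL
  for (off in 0:config$tgg_max_offset) {
    if (substr(win, off + 1L, off + 3L) != "TGG") next
    q <- substr(win, off + 1L, off + w)
    if (nchar(q) < config$pbs_min_exact) next
    for (i in seq_len(nrow(trnas))) {
      t <- trnas$residues[i]
      r <- revcomp(substr(t, nchar(t) - w + 1L, nchar(t)))
      ce <- constrained_edit(q, r, config$fuzzy_max_diffs, config$fuzzy_max_indels)
      if (is.null(ce) || ce$aligned_len < config$pbs_min_exact) next
      cand <- c(ce, list(off = off, id = trnas$id[i], iso = trnas$isoacceptor[i]))
      if (is.null(best) ||
          cand$diffs + cand$indels < best$diffs + best$indels ||
          (cand$diffs + cand$indels == best$diffs + best$indels &&
           (cand$indels < best$indels ||
            (cand$indels == best$indels && cand$id < best$id)))) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  from <- element$ltr$five[2] + best$off + 1L
  new_primer_call("fuzzy_tRNA", best$id, best$iso, best$aligned_len,
                  diffs = best$diffs, indels = best$indels,
                  start = from, end = from + best$aligned_len - 1L,
                  offset = best$off)
}

#' Self-primer detection
#'
#' Detects priming by a fragment of the element's own 5' LTR: an exact
#' occurrence, anywhere inside the 5' LTR, of the reverse complement of a
#' downstream stretch of at least `self_primer_min` bp starting 0--5 bp
#' after the LTR. The longest such complementary stretch wins.
#'
#' @inheritParams find_exact_pbs
#' @return A `primer_call` of mode `self`, or `NULL`.
#' @export
find_self_primer <- function(element, config = pipeline_config()) {
  if (is.null(element$ltr)) stop("PBS requires 5' LTR")
  s <- element$seq$residues
  ltr5 <- substr(s, element$ltr$five[1], element$ltr$five[2])
  base <- element$ltr$five[2]
  for (len in seq(config$self_primer_max, config$self_primer_min)) {
    for (off in 0:config$tgg_max_offset) {
      from <- base + off + 1L
      q <- substr(s, from, from + len - 1L)
      if (nchar(q) < len) next
      if (grepl(revcomp(q), ltr5, fixed = TRUE)) {
        return(new_primer_call("self", match_len = len,
                               start = from, end = from + len - 1L,
                               offset = off))
      }
    }
  }
  NULL
}

#' Type the primer binding site of an element
#'
#' Runs the detectors in precedence order full tRNA > half tRNA > fuzzy
#' tRNA > self-primer; the first successful detector wins and `none` is
#' returned when nothing fires.
#'
#' @inheritParams find_exact_pbs
#' @return A `primer_call`; its `mode` is one of `full_tRNA`, `half_tRNA`,
#'   `fuzzy_tRNA`, `self`, `none`.
#' @export
call_pbs <- function(element, trnas, config = pipeline_config()) {
  call <- find_exact_pbs(element, trnas, config)
  if (is.null(call)) call <- find_half_trna_pbs(element, trnas, config)
  if (is.null(call)) call <- find_fuzzy_pbs(element, trnas, config)
  if (is.null(call)) call <- find_self_primer(element, config)
  if (is.null(call)) call <- new_primer_call("none")
  call
}
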