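#' Find the LTR pair of a candidate element
#'
#' Seeds exact 20-mer matches between the first and last 8 kb of the
#' sequence, groups colinear seeds on the same diagonal, extends each
#' candidate block outward under an x-drop rule, optionally snaps the
#' boundaries to TG/CA termini, and keeps the highest-similarity pair that
#' satisfies the structural constraints (LTR length, inter-LTR distance,
#' minimum similarity, and TG..CA termini when `require_tg_ca` is set).
#' Ties are broken by longer LTR, then leftmost 5' start.
#'
#' @param seq an `ltr_seq` record or a DNA string.
#' @param config an [pipeline_config()].
#' @param k seed length.
#' @return A list of class `ltr_pair` with elements `five` and `three`
#'   (1-based closed intervals), `similarity` (percent) and `termini_ok`,
#'   or `NULL` when no pair qualifies.
#' @export
find_ltr_pair <- function(seq, config = pipeline_config(), k = 20) {
  s <- if (inherits(seq, "ltr_seq")) seq$residues else seq
  n <- nchar(s)
  if (n < config$inter_ltr_min + 2 * config$ltr_min_len) return(NULL)
  zone <- min(8000L, n)
  head_end <- zone
  tail_start <- max(1L, n - zone + 1L)
  x <- chars(s)

  seeds <- seed_matches(s, head_end, tail_start, n, k,
                        min_d = config$inter_ltr_min)
  if (is.null(seeds) || !nrow(seeds)) return(NULL)
  seeds$diag <- seeds$tpos - seeds$hpos
  best <- NULL
  for (d in unique(seeds$diag)) {
    sd <- seeds[seeds$diag == d, , drop = FALSE]
    sd <- sd[order(sd$hpos), , drop = FALSE]
    # split runs with gaps > 400 bp between consecutive seeds
    grp <- cumsum(c(0, diff(sd$hpos) > 400))
    for (g in unique(grp)) {
      blk <- sd[grp == g, , drop = FALSE]
      h1 <- min(blk$hpos); h2 <- max(blk$hpos) + k - 1L
      cand <- extend_block(x, h1, h2, d, n)
      cand <- refine_candidate(s, cand, d, n, config)
      if (is.null(cand)) next
      if (is.null(best) || better_pair(cand, best)) best <- cand
    }
  }
  best
}

# exact k-mer matches between s[1..head_end] and s[tail_start..n] whose
# start distance is at least min_d (drops self-matches when zones overlap)
seed_matches <- function(s, head_end, tail_start, n, k, min_d = 0) {
  if (head_end < k || n - tail_start + 1 < k) return(NULL)
  hstarts <- seq_len(head_end - k + 1L)
  tstarts <- seq.int(tail_start, n - k + 1L)
  hk <- substring(s, hstarts, hstarts + k - 1L)
  tk <- substring(s, tstarts, tstarts + k - 1L)
  idx <- split(hstarts, hk)
  hits <- lapply(seq_along(tstarts), function(i) {
    hp <- idx[[tk[i]]]
    if (!is.null(hp)) hp <- hp[tstarts[i] - hp >= min_d]
    if (is.null(hp) || !length(hp)) return(NULL)
    data.frame(hpos = hp, tpos = tstarts[i])
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# extend [h1,h2] along diagonal d with +1 match / -2 mismatch x-drop (drop 8)
extend_block <- function(x, h1, h2, d, n) {
  sc <- 0; best <- 0; bh <- h1
  i <- h1 - 1L
  while (i >= 1L && i + d >= 1L && sc > best - 8) {
    sc <- sc + if (x[i] == x[i + d]) 1 else -2
    if (sc > best) { best <- sc; bh <- i }
    i <- i - 1L
  }
  h1 <- bh
  sc <- 0; best <- 0; bh <- h2
  i <- h2 + 1L
  while (i <= n && i + d <= n && sc > best - 8) {
    sc <- sc + if (x[i] == x[i + d]) 1 else -2
    if (sc > best) { best <- sc; bh <- i }
    i <- i + 1L
  }
  list(h1 = h1, h2 = bh)
}

refine_candidate <- function(s, cand, d, n, config) {
  h1 <- cand$h1; h2 <- cand$h2
  # snap to TG start / CA end near the extended boundaries when termini are
  # required (the x-drop extension can stop a few bases short when
  # substitutions cluster at an LTR boundary)
  if (config$require_tg_ca) {
    h1 <- snap_start(s, h1, d)
    h2 <- snap_end(s, h2, d, n)
  }
  len <- h2 - h1 + 1L
  t1 <- h1 + d; t2 <- h2 + d
  if (len < config$ltr_min_len || len > config$ltr_max_len) return(NULL)
  if (d < config$inter_ltr_min || d > config$inter_ltr_max) return(NULL)
  if (t1 <= h2) return(NULL)  # copies must not overlap
  if (t2 > n) return(NULL)
  five <- substr(s, h1, h2)
  three <- substr(s, t1, t2)
  termini_ok <- startsWith(five, "TG") && endsWith(three, "CA")
  if (config$require_tg_ca && !termini_ok) return(NULL)
  sim <- ltr_similarity(five, three, config)
  if (sim < config$ltr_min_similarity) return(NULL)
  structure(list(five = c(h1, h2), three = c(t1, t2),
                 similarity = sim, termini_ok = termini_ok),
            class = "ltr_pair")
}

snap_start <- function(s, h1, d) {
  for (off in 0:8) {
    for (sgn in c(0L, off, -off)) {
      p <- h1 + sgn
      if (p >= 1 && p + d >= 1 && substr(s, p, p + 1) == "TG") return(p)
    }
  }
  h1
}

snap_end <- function(s, h2, d, n) {
  for (off in 0:8) {
    for (sgn in c(0L, off, -off)) {
      p <- h2 + sgn
      if (p + d <= n && p >= 1 && substr(s, p + d - 1, p + d) == "CA") return(p)
    }
  }
  h2
}

better_pair <- function(a, b) {
  if (abs(a$similarity - b$similarity) > 1e-9) return(a$similarity > b$similarity)
  la <- a$five[2] - a$five[1]; lb <- b$five[2] - b$five[1]
  if (la != lb) return(la > lb)
  a$five[1] < b$five[1]
}

#' @export
print.ltr_pair <- function(x, ...) {
  cat(sprintf("<ltr_pair> 5' [%d,%d]  3' [%d,%d]  similarity %.1f%%  termini %s\n",
              x$five[1], x$five[2], x$three[1], x$three[2], x$similarity,
              if (x$termini_ok) "TG..CA" else "non-canonical"))
  invisible(x)
}

#' Detect a target site duplication in the element flanks
#'
#' Compares the last L bases of the left flank with the first L bases of the
#' right flank for L = 6, 5, 4 (longest first) and returns the first exact
#' match.
#'
#' @param left_flank,right_flank host flanking sequence.
#' @param config an [pipeline_config()]; `tsd_lengths` gives the lengths
#'   tried (descending).
#' @return A list of class `tsd_call` (`length`, `left_seq`, `right_seq`,
#'   `exact`) or `NULL`. Flanks shorter than the smallest length give `NULL`
#'   with a warning.
#' @export
detect_tsd <- function(left_flank, right_flank, config = pipeline_config()) {
  lens <- sort(config$tsd_lengths, decreasing = TRUE)
  if (nchar(left_flank) < min(lens) || nchar(right_flank) < min(lens)) {
    warning("flanks too short for TSD detection")
    return(NULL)
  }
  for (L in lens) {
    if (nchar(left_flank) < L || nchar(right_flank) < L) next
    left <- substr(left_flank, nchar(left_flank) - L + 1L, nchar(left_flank))
    right <- substr(right_flank, 1L, L)
    if (left == right) {
      return(structure(list(length = L, left_seq = left, right_seq = right,
                            exact = TRUE), class = "tsd_call"))
    }
  }
  NULL
}

#' Enumerate the theoretical TSD sequence space
#'
#' All DNA words of the given length; for the common 5 bp target site
#' duplications this space has 4^5 = 1024 members, the yardstick against
#' which observed TSD diversity is judged.
#'
#' @param length word length.
#' @return Character vector of all 4^length DNA words.
#' @examples
#' length(tsd_sequence_space(5))  # 1024
#' @export
tsd_sequence_space <- function(length = 5) {
  stopifnot(length >= 1, length <= 12)
  grid <- do.call(expand.grid, c(rep(list(DNA_BASES), length),
                                 stringsAsFactors = FALSE))
  # column 1 varies slowest so words come out in lexicographic order
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  ord <- do.call(order, as.list(grid))
  apply(grid[ord, , drop = FALSE], 1, paste, collapse = "")
}

#' Validate an element and collect QC flags
#'
#' Flags: `ambiguous_bases` when the N count exceeds `max_n`; `bad_termini`
#' when the 5' LTR does not start with TG or the 3' LTR does not end with CA;
#' `no_polyprotein` when no domain architecture was found;
#' `nested_insertion_suspect` when a second LTR-like pair lies strictly
#' inside the internal region. An element is accepted iff no flags are
#' raised.
#'
#' @param record an `ltr_element` record (see [annotate_elements()]).
#' @param config an [pipeline_config()].
#' @return Character vector of QC flags (possibly empty).
#' @export
validate_element <- function(record, config = pipeline_config()) {
  flags <- character()
  s <- record$seq$residues
  n_count <- nchar(gsub("[^N]", "", s))
  if (n_count > config$max_n) flags <- c(flags, "ambiguous_bases")
  if (!is.null(record$ltr)) {
    five <- substr(s, record$ltr$five[1], record$ltr$five[2])
    three <- substr(s, record$ltr$three[1], record$ltr$three[2])
    if (!startsWith(five, "TG") || !endsWith(three, "CA"))
      flags <- c(flags, "bad_termini")
    internal <- substr(s, record$ltr$five[2] + 1L, record$ltr$three[1] - 1L)
    if (nchar(internal) >= config$inter_ltr_min + 2 * config$ltr_min_len) {
      inner_cfg <- config
      inner_cfg$require_tg_ca <- FALSE
      if (!is.null(find_ltr_pair(internal, inner_cfg)))
        flags <- c(flags, "nested_insertion_suspect")
    }
  }
  if (is.null(record$architecture) || !nrow(record$architecture$calls))
    flags <- c(flags, "no_polyprotein")
  flags
}
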