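#' Assign a lineage by weighted best-hit voting
#'
#' Each core domain call (PROT, INT, RT, RH; GAG and chromodomains are too
#' variable and are excluded from voting) contributes the lineage path of
#' its best reference hit, weighted by alignment score. The path with the
#' largest summed weight wins (ties broken by deeper path, then
#' lexicographically); `vote_share` is its fraction of the total weight.
#' A superfamily conflict among the votes, or between the votes and the
#' architecture template, propagates the `chimera` flag.
#'
#' @param architecture a `domain_architecture` (see
#'   [validate_architecture()]).
#' @param config an [pipeline_config()]; calls with `vote_share` below
#'   `vote_confidence` are flagged `low_confidence`.
#' @return A list of class `lineage_call`: `superfamily`, `lineage`,
#'   `vote_share`, `flags`.
#' @export
vote_lineage <- function(architecture, config = pipeline_config()) {
  calls <- architecture$calls
  vote_types <- c("PROT", "INT", "RT", "RH")
  if (is.null(calls) || !nrow(calls)) stop("unclassifiable: no core domains")
  v <- calls[calls$domain_type %in% vote_types, , drop = FALSE]
  if (!nrow(v)) stop("unclassifiable: no core domains")
  w <- tapply(v$score, v$lineage, sum)
  total <- sum(w)
  depth <- lengths(strsplit(names(w), "|", fixed = TRUE))
  ord <- order(-w, -depth, names(w))
  win <- names(w)[ord[1]]
  share <- unname(w[win]) / total
  flags <- character()
  sf_votes <- unique(vapply(strsplit(names(w)[w > 0], "|", fixed = TRUE),
                            `[`, character(1), 1))
  sf_win <- strsplit(win, "|", fixed = TRUE)[[1]][1]
  if (length(sf_votes) > 1 ||
      (architecture$superfamily != "undetermined" &&
       sf_win != architecture$superfamily) ||
      "chimera" %in% architecture$flags) {
    flags <- c(flags, "chimera")
  }
  if (share < config$vote_confidence) flags <- c(flags, "low_confidence")
  structure(list(superfamily = sf_win, lineage = win, vote_share = share,
                 flags = flags), class = "lineage_call")
}

#' @export
print.lineage_call <- function(x, ...) {
  cat(sprintf("<lineage_call> %s (vote share %.2f)", x$lineage, x$vote_share))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Load the structural-feature expectation rules
#'
#' The shipped table transcribes the characteristic features of each
#' lineage: expected chromodomain type (chromodomains occur in chromoviruses
#' only, with the CR variant confined to the CRM clade), expected aRH
#' position (between PROT and RT for TatI/TatII, after INT for TatIII,
#' between RH and INT for Ogre/Retand) and expected PBS type per lineage.
#' Users may edit or extend the TSV.
#'
#' @param path TSV with columns `lineage`, `expected_chromodomain`,
#'   `expected_arh_position`, `expected_pbs`; default the shipped table.
#' @return data.frame of rules.
#' @export
read_lineage_rules <- function(path = system.file("extdata", "lineage_rules.tsv",
                                                  package = "ltrclass")) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Check structural features against lineage expectations
#'
#' @param lineage a `lineage_call` (or a lineage path string).
#' @param features list with `chromodomain` (`CHD`/`CHDCR`/`none`),
#'   `arh_position` (`none`/`PROT_RT`/`RH_INT`/`after_INT`/`other`), and
#'   `pbs` (a `primer_call` or `NULL`).
#' @param rules data.frame from [read_lineage_rules()].
#' @return Character vector of consistency flags among
#'   `chromodomain_mismatch`, `arh_position_mismatch`, `pbs_unexpected`
#'   (empty when all expectations hold). Lineages absent from the rules
#'   table skip all checks with a warning.
#' @export
check_consistency <- function(lineage, features, rules = read_lineage_rules()) {
  path <- if (inherits(lineage, "lineage_call")) lineage$lineage else lineage
  row <- rules[rules$lineage == path, , drop = FALSE]
  if (!nrow(row)) {
    warning("no expectation rules for lineage ", path, "; checks skipped")
    return(character())
  }
  flags <- character()
  chd_allowed <- trimws(strsplit(row$expected_chromodomain, ",")[[1]])
  chd <- features$chromodomain %||% "none"
  if (!"any" %in% chd_allowed && !chd %in% chd_allowed)
    flags <- c(flags, "chromodomain_mismatch")
  arh_expected <- trimws(row$expected_arh_position)
  arh <- features$arh_position %||% "none"
  if (arh_expected != "any" && arh != arh_expected)
    flags <- c(flags, "arh_position_mismatch")
  pbs_allowed <- trimws(strsplit(row$expected_pbs, ",")[[1]])
  if (!"any" %in% pbs_allowed) {
    pbs <- features$pbs
    token <- if (is.null(pbs) || pbs$mode == "none") "none"
      else switch(pbs$mode,
                  full_tRNA = paste0("full:", pbs$isoacceptor),
                  half_tRNA = paste0("half:", pbs$isoacceptor),
                  fuzzy_tRNA = paste0("fuzzy:", pbs$isoacceptor),
                  self = "self")
    mode_only <- sub(":.*$", "", token)
    ok <- token %in% pbs_allowed | mode_only %in% pbs_allowed
    if (!ok) flags <- c(flags, "pbs_unexpected")
  }
  flags
}

#' Detect the aromatic cage motif in a chromodomain
#'
#' HP1-like chromodomains bind methylated histone tails through an aromatic
#' cage of three conserved aromatic residues (F, Y or W). The query
#' chromodomain protein is aligned locally to an annotated CHD reference
#' and the residues at the three annotated cage columns are checked for
#' membership in {F, Y, W}. Columns not covered by the alignment are
#' reported `unknown`; the cage is present only when all three sites are.
#'
#' @param chd_protein amino-acid string of the element's chromodomain.
#' @param refdb an `ltr_refdb` with `cage_columns` annotated on at least one
#'   CHD entry.
#' @param config an [pipeline_config()].
#' @return A list with `sites` (character vector of three values among
#'   `present`, `absent`, `unknown`) and `cage` (logical).
#' @export
detect_aromatic_cage <- function(chd_protein, refdb, config = pipeline_config()) {
  refs <- intersect(names(refdb$cage_columns),
                    refdb$entries$name[refdb$entries$domain_type == "CHD"])
  if (!length(refs)) stop("reference database has no CHD entry with cage columns")
  al <- align_protein_local(chd_protein, refdb$proteins[refs], config)
  best <- which.max(al$score)
  ref_name <- refs[best]
  cols <- refdb$cage_columns[[ref_name]]
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(refdb$proteins[[ref_name]]),
    Biostrings::AAString(chd_protein), type = "local",
    substitutionMatrix = prot_matrix(config$prot_matrix),
    gapOpening = config$prot_gap_open, gapExtension = config$prot_gap_extend)
  rchars <- chars(as.character(Biostrings::alignedPattern(pa)))
  qchars <- chars(as.character(Biostrings::alignedSubject(pa)))
  rpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  sites <- character(3)
  for (k in seq_along(cols)) {
    res <- NA_character_
    ri <- rpos
    for (ci in seq_along(rchars)) {
      if (rchars[ci] != "-") ri <- ri + 1L
      if (ri == cols[k] && rchars[ci] != "-") {
        res <- qchars[ci]
        break
      }
    }
    sites[k] <- if (is.na(res) || res == "-") "unknown"
      else if (res %in% c("F", "Y", "W")) "present" else "absent"
  }
  list(sites = sites, cage = all(sites == "present"), reference = ref_name)
}

#' Per-element report and corpus summaries
#'
#' @param elements list of annotated `ltr_element` records.
#' @return A list of class `ltr_report`: `report` (one row per element with
#'   columns element, superfamily, lineage, ltr_similarity, tsd_len,
#'   tsd_seq, pbs_mode, pbs_trna, domains_in_order, eorf_labels, qc_flags)
#'   and `summary` (lineage counts, PBS mode, TSD length and eORF label
#'   frequency tables).
#' @export
format_report <- function(elements) {
  rows <- lapply(elements, function(el) {
    eorfs <- el$eorfs
    labels <- if (!is.null(eorfs) && nrow(eorfs)) {
      keep <- !eorfs$excluded & !is.na(eorfs$label)
      paste(eorfs$label[keep], collapse = ",")
    } else ""
    data.frame(
      element = el$seq$id,
      superfamily = if (!is.null(el$architecture)) el$architecture$superfamily else NA,
      lineage = if (!is.null(el$lineage)) el$lineage$lineage else NA,
      ltr_similarity = if (!is.null(el$ltr)) round(el$ltr$similarity, 2) else NA,
      tsd_len = if (!is.null(el$tsd)) el$tsd$length else NA,
      tsd_seq = if (!is.null(el$tsd)) el$tsd$left_seq else NA,
      pbs_mode = if (!is.null(el$pbs)) el$pbs$mode else "none",
      pbs_trna = if (!is.null(el$pbs) && !is.null(el$pbs$isoacceptor))
        el$pbs$isoacceptor else NA,
      domains_in_order = if (!is.null(el$architecture))
        paste(el$architecture$calls$domain_type, collapse = "-") else "",
      eorf_labels = labels,
      qc_flags = paste(el$qc_flags, collapse = ","),
      stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else data.frame(
    element = character(), superfamily = character(), lineage = character(),
    ltr_similarity = numeric(), tsd_len = integer(), tsd_seq = character(),
    pbs_mode = character(), pbs_trna = character(),
    domains_in_order = character(), eorf_labels = character(),
    qc_flags = character(), stringsAsFactors = FALSE)
  all_labels <- unlist(strsplit(report$eorf_labels[nzchar(report$eorf_labels)], ","))
  summary <- list(
    n = nrow(report),
    lineage_counts = table(report$lineage, useNA = "no"),
    pbs_mode_freq = if (nrow(report)) prop.table(table(report$pbs_mode)) else table(character()),
    tsd_len_freq = if (any(!is.na(report$tsd_len)))
      prop.table(table(report$tsd_len)) else table(integer()),
    eorf_label_counts = table(all_labels))
  structure(list(report = report, summary = summary), class = "ltr_report")
}

#' @export
print.ltr_report <- function(x, ...) {
  cat(sprintf("<ltr_report> %d elements\n", x$summary$n))
  if (x$summary$n) {
    cat("lineages:\n"); print(x$summary$lineage_counts)
    cat("PBS modes:\n"); print(round(x$summary$pbs_mode_freq, 3))
  }
  invisible(x)
}

#' Write the per-element report as TSV
#'
#' @param report an `ltr_report` (or its `report` data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- if (inherits(report, "ltr_report")) report$report else report
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
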