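#' Annotate one element
#'
#' Runs the full per-element pipeline: LTR pair detection, TSD detection
#' from the flanks, translated domain search with frameshift-tolerant
#' chaining and architecture validation, PBS typing, extra-ORF detection
#' with tandem-repeat filtering, lineage voting with structural-feature
#' consistency checks, aromatic-cage inspection of any chromodomain, and
#' final QC flagging. Failures of individual stages become QC flags, never
#' errors, so batch runs always complete.
#'
#' @param seq an `ltr_seq` record.
#' @param refdb an `ltr_refdb`.
#' @param trnas a `trna_library` (prepared or not; CCA tails are ensured).
#' @param config an [pipeline_config()].
#' @param rules lineage expectation rules (see [read_lineage_rules()]).
#' @return An `ltr_element` record.
#' @export
annotate_element <- function(seq, refdb, trnas, config = pipeline_config(),
                             rules = read_lineage_rules()) {
  el <- list(seq = seq, ltr = NULL, tsd = NULL, architecture = NULL,
             pbs = NULL, eorfs = NULL, arrays = NULL, lineage = NULL,
             cage = NULL, qc_flags = character())
  class(el) <- "ltr_element"
  el$ltr <- find_ltr_pair(seq, config)
  if (nzchar(seq$left_flank) && nzchar(seq$right_flank)) {
    el$tsd <- tryCatch(detect_tsd(seq$left_flank, seq$right_flank, config),
                       warning = function(w) NULL)
  }
  hits <- scan_domains(seq, refdb, config)
  calls <- chain_hits(hits, config)
  el$architecture <- validate_architecture(calls)
  if (!is.null(el$ltr)) {
    el$pbs <- tryCatch(call_pbs(el, prepare_trnas(trnas), config),
                       error = function(e) new_primer_call("none"))
  }
  el$arrays <- find_tandem_arrays(seq$residues, config)
  orfs <- find_orfs(seq$residues, config$eorf_min_codons, config$eorf_require_atg)
  if (nrow(orfs) && nrow(calls)) {
    poly <- c(min(calls$start), max(calls$end))
    orfs$label <- vapply(seq_len(nrow(orfs)), function(i)
      label_eorf(orfs[i, ], poly), character(1))
    orfs <- orfs[!is.na(orfs$label), , drop = FALSE]
    orfs <- filter_eorfs(orfs, el$arrays)
  } else {
    orfs <- orfs[0, , drop = FALSE]
    orfs$label <- character()
    orfs <- filter_eorfs(orfs, el$arrays)
  }
  el$eorfs <- orfs
  if (nrow(calls)) {
    el$lineage <- tryCatch(vote_lineage(el$architecture, config),
                           error = function(e) NULL)
  }
  if (!is.null(el$lineage)) {
    feats <- list(chromodomain = el$architecture$chromodomain,
                  arh_position = el$architecture$arh_position,
                  pbs = el$pbs)
    cons <- tryCatch(
      suppressWarnings(check_consistency(el$lineage, feats, rules)),
      error = function(e) character())
    el$lineage$flags <- union(el$lineage$flags, cons)
    chd_call <- which(el$architecture$calls$domain_type == "CHD")
    if (length(chd_call)) {
      el$cage <- tryCatch(
        detect_aromatic_cage(el$architecture$calls$qseq[chd_call[1]],
                             refdb, config),
        error = function(e) NULL)
    }
  }
  el$qc_flags <- sort(unique(c(validate_element(el, config),
                               el$architecture$flags)))
  el
}

#' Annotate a batch of elements
#'
#' @param seqs list of `ltr_seq` records (e.g. from [read_dna_fasta()] or a
#'   corpus from [make_corpus()]).
#' @inheritParams annotate_element
#' @return List of `ltr_element` records (class `ltr_annotation`).
#' @export
annotate_elements <- function(seqs, refdb, trnas, config = pipeline_config(),
                              rules = read_lineage_rules()) {
  if (inherits(seqs, "ltr_corpus")) seqs <- seqs$elements
  trnas <- prepare_trnas(trnas)
  out <- lapply(seqs, function(s) annotate_element(s, refdb, trnas, config, rules))
  class(out) <- "ltr_annotation"
  out
}

#' @export
print.ltr_element <- function(x, ...) {
  cat(sprintf("<ltr_element> %s (%d bp)\n", x$seq$id, nchar(x$seq$residues)))
  if (!is.null(x$ltr))
    cat(sprintf("  LTRs: [%d,%d] / [%d,%d], similarity %.1f%%\n",
                x$ltr$five[1], x$ltr$five[2], x$ltr$three[1], x$ltr$three[2],
                x$ltr$similarity))
  if (!is.null(x$tsd)) cat(sprintf("  TSD: %s (%d bp)\n", x$tsd$left_seq, x$tsd$length))
  if (!is.null(x$architecture))
    cat(sprintf("  domains: %s (%s)\n",
                paste(x$architecture$calls$domain_type, collapse = "-"),
                x$architecture$superfamily))
  if (!is.null(x$pbs)) cat(sprintf("  PBS: %s%s\n", x$pbs$mode,
    if (!is.null(x$pbs$isoacceptor) && !is.na(x$pbs$isoacceptor %||% NA))
      paste0(" (", x$pbs$isoacceptor, ")") else ""))
  if (!is.null(x$lineage))
    cat(sprintf("  lineage: %s (vote %.2f)\n", x$lineage$lineage,
                x$lineage$vote_share))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ltr_annotation <- function(x, ...) {
  cat(sprintf("<ltr_annotation> %d elements\n", length(x)))
  print(format_report(x))
  invisible(x)
}
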