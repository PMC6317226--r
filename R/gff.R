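# GFF3 output of annotated elements.

#' Collect annotation features of elements as a GRanges
#'
#' One `LTR_retrotransposon` parent row per element plus child rows for the
#' two LTRs (`long_terminal_repeat`), the primer binding site
#' (`primer_binding_site`), each domain call (`protein_match`) and each
#' retained extra ORF (`ORF`). Coordinates are 1-based inclusive on the
#' element sequence. The TSD is carried as `tsd_seq`/`tsd_len` attributes of
#' the parent row because its bases lie in the host flanks, outside the
#' element's own coordinate system.
#'
#' @param elements a list of annotated `ltr_element` records
#'   (see [annotate_elements()]).
#' @return A [GenomicRanges::GRanges] with `type`, `ID`, `Parent` and
#'   attribute metadata columns.
#' @export
element_features <- function(elements) {
  rows <- list()
  add <- function(seqid, start, end, type, id, parent = NA_character_,
                  strand = "+", ...) {
    rows[[length(rows) + 1L]] <<- c(
      list(seqid = seqid, start = start, end = end, type = type, id = id,
           parent = parent, strand = strand), list(...))
  }
  for (el in elements) {
    n <- nchar(el$seq$residues)
    sid <- el$seq$id
    pid <- paste0(sid, ":element")
    add(sid, 1L, n, "LTR_retrotransposon", pid,
        lineage = if (!is.null(el$lineage)) el$lineage$lineage else NA_character_,
        ltr_similarity = if (!is.null(el$ltr)) round(el$ltr$similarity, 2) else NA_real_,
        tsd_seq = if (!is.null(el$tsd)) el$tsd$left_seq else NA_character_,
        tsd_len = if (!is.null(el$tsd)) el$tsd$length else NA_integer_,
        qc_flags = paste(el$qc_flags, collapse = ","))
    if (!is.null(el$ltr)) {
      add(sid, el$ltr$five[1], el$ltr$five[2], "long_terminal_repeat",
          paste0(sid, ":ltr5"), pid)
      add(sid, el$ltr$three[1], el$ltr$three[2], "long_terminal_repeat",
          paste0(sid, ":ltr3"), pid)
    }
    if (!is.null(el$pbs) && el$pbs$mode %in% c("full_tRNA", "half_tRNA", "fuzzy_tRNA", "self")) {
      add(sid, el$pbs$start, el$pbs$end, "primer_binding_site",
          paste0(sid, ":pbs"), pid,
          pbs_mode = el$pbs$mode, pbs_trna = el$pbs$trna_id %||% NA_character_)
    }
    if (!is.null(el$architecture) && nrow(el$architecture$calls)) {
      calls <- el$architecture$calls
      for (i in seq_len(nrow(calls))) {
        add(sid, calls$start[i], calls$end[i], "protein_match",
            paste0(sid, ":", calls$domain_type[i], i), pid,
            strand = calls$strand[i],
            domain_type = calls$domain_type[i], best_ref = calls$best_ref[i],
            lineage = calls$lineage[i], identity = round(calls$identity[i], 2))
      }
    }
    if (!is.null(el$eorfs) && nrow(el$eorfs)) {
      keep <- !el$eorfs$excluded & !is.na(el$eorfs$label)
      orfs <- el$eorfs[keep, , drop = FALSE]
      for (i in seq_len(nrow(orfs))) {
        add(sid, orfs$start[i], orfs$end[i], "ORF",
            paste0(sid, ":eorf", i), pid, strand = orfs$strand[i],
            eorf_label = orfs$label[i])
      }
    }
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges()))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    base <- data.frame(seqid = r$seqid, start = r$start, end = r$end,
                       type = r$type, ID = r$id, strand = r$strand,
                       stringsAsFactors = FALSE)
    extra <- r[setdiff(names(r), c("seqid", "start", "end", "type", "id", "strand", "parent"))]
    for (k in c("lineage", "ltr_similarity", "tsd_seq", "tsd_len", "qc_flags",
                "pbs_mode", "pbs_trna", "domain_type", "best_ref", "identity",
                "eorf_label")) {
      base[[k]] <- if (!is.null(extra[[k]])) extra[[k]] else NA
    }
    base$parent <- r$parent
    base
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- S4Vectors::mcols(gr)$ID  # placeholder, fixed below
  parent <- ifelse(is.na(df$parent), "", df$parent)
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(parent, function(p) if (nzchar(p)) p else character()))
  for (k in c("lineage", "ltr_similarity", "tsd_seq", "tsd_len", "qc_flags",
              "pbs_mode", "pbs_trna", "domain_type", "best_ref", "identity",
              "eorf_label")) {
    S4Vectors::mcols(gr)[[k]] <- df[[k]]
  }
  gr
}

#' Write annotated elements to a GFF3 file
#'
#' @param elements list of annotated `ltr_element` records.
#' @param path output file.
#' @return `path`, invisibly. Empty input yields a header-only file.
#' @export
write_gff3 <- function(elements, path) {
  gr <- element_features(elements)
  if (!length(gr)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
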