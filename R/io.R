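#' Read DNA sequences from a FASTA file
#'
#' Records keep file order; residues are upper-cased and RNA `U` is mapped to
#' `T`. Returns a list of `ltr_seq` objects (id, residues, empty flanks).
#'
#' @param path FASTA file.
#' @return A list of [as_ltr_seq()] objects; empty file gives an empty list.
#' @export
read_dna_fasta <- function(path) {
  if (file.size(path) == 0) return(list())
  x <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(x))) stop("duplicate FASTA ids in ", path)
  lapply(seq_along(x), function(i) {
    res <- toupper(as.character(x[[i]]))
    res <- chartr("U", "T", res)
    if (grepl("[^ACGTN]", res))
      stop("record ", names(x)[i], " contains non-DNA characters")
    as_ltr_seq(names(x)[i], res)
  })
}

#' Construct a genomic sequence record
#'
#' @param id sequence identifier (unique within a collection).
#' @param residues DNA string over A,C,G,T,N.
#' @param left_flank,right_flank optional flanking host sequence (used for
#'   target-site-duplication detection).
#' @return An object of class `ltr_seq`.
#' @export
as_ltr_seq <- function(id, residues, left_flank = "", right_flank = "") {
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("residues must be non-empty")
  if (grepl("[^ACGTN]", residues)) stop("residues restricted to A,C,G,T,N")
  structure(list(id = id, residues = residues,
                 left_flank = toupper(left_flank),
                 right_flank = toupper(right_flank)),
            class = "ltr_seq")
}

#' @export
print.ltr_seq <- function(x, ...) {
  cat(sprintf("<ltr_seq> %s: %d bp (flanks %d/%d bp)\n", x$id,
              nchar(x$residues), nchar(x$left_flank), nchar(x$right_flank)))
  invisible(x)
}

#' Write sequences to FASTA
#'
#' @param seqs a named character vector, or a list of `ltr_seq` objects.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1]], "ltr_seq")) {
    seqs <- stats::setNames(vapply(seqs, `[[`, character(1), "residues"),
                            vapply(seqs, `[[`, character(1), "id"))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Parse a REXdb-style reference protein name
#'
#' Names follow `<superfamilyToken>-<domainType>__<elementName>`, e.g.
#' `Ty1-RT__REXdb_ID3879` is the RT domain of element `REXdb_ID3879` from a
#' Ty1/copia element.
#'
#' @param name reference protein name.
#' @return A list with `superfamily` token (`Ty1`/`Ty3`), `domain_type`,
#'   and `element_name`.
#' @examples
#' parse_rexdb_name("Ty1-RT__REXdb_ID3879")
#' @export
parse_rexdb_name <- function(name) {
  if (!grepl("__", name, fixed = TRUE))
    stop("unparseable reference name: ", name)
  parts <- regmatches(name, regexpr("__", name, fixed = TRUE), invert = TRUE)[[1]]
  prefix <- parts[1]
  element <- parts[2]
  if (!grepl("-", prefix, fixed = TRUE) || !nzchar(element))
    stop("unparseable reference name: ", name)
  dash <- regexpr("-", prefix, fixed = TRUE)
  list(superfamily = substr(prefix, 1, dash - 1),
       domain_type = substr(prefix, dash + 1, nchar(prefix)),
       element_name = element)
}

#' Format a REXdb-style reference protein name
#'
#' Inverse of [parse_rexdb_name()].
#'
#' @param superfamily superfamily token (`Ty1` or `Ty3`).
#' @param domain_type domain type (GAG, PROT, RT, RH, aRH, INT, CHD, CHDCR).
#' @param element_name element identifier.
#' @return The formatted name.
#' @export
format_rexdb_name <- function(superfamily, domain_type, element_name) {
  paste0(superfamily, "-", domain_type, "__", element_name)
}

DOMAIN_TYPES <- c("GAG", "PROT", "INT", "RT", "RH", "aRH", "CHD", "CHDCR")

# Fixed lineage vocabulary (levels below the superfamily).
LINEAGE_LEVELS <- c(
  "chromovirus", "non-chromovirus", "OTA", "Tat",
  "Chlamyvir", "Tcn1", "Tekay", "Reina", "Galadriel", "CRM",
  "Phygy", "Selgy", "Athila", "TatI", "TatII", "TatIII", "Ogre", "Retand",
  "Ale", "Alesia", "Angela", "Bianca", "Bryco", "Gymco-I", "Gymco-II",
  "Gymco-III", "Gymco-IV", "Ikeros", "Ivana", "Lyco", "Osser", "SIRE",
  "TAR", "Tork")

SUPERFAMILIES <- c("Ty1/copia", "Ty3/gypsy")

#' Read an element-to-lineage classification table
#'
#' Expects a TSV with columns `element_name` and `lineage_path`; lineage paths
#' use the pipe-delimited grammar `superfamily|level1|...|levelN`, e.g.
#' `Ty3/gypsy|non-chromovirus|OTA|Tat|Ogre`.
#'
#' @param path TSV file.
#' @param extra_levels additional accepted level names beyond the built-in
#'   vocabulary.
#' @return A named character vector mapping element names to lineage paths,
#'   with attribute `unknown_levels` listing any levels outside the vocabulary
#'   (these also raise a warning).
#' @export
read_lineage_table <- function(path, extra_levels = character()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("element_name", "lineage_path") %in% names(df)))
    stop("lineage table needs columns element_name and lineage_path")
  if (anyDuplicated(df$element_name))
    stop("duplicate element_name in lineage table: ",
         paste(unique(df$element_name[duplicated(df$element_name)]), collapse = ", "))
  vocab <- c(LINEAGE_LEVELS, extra_levels)
  unknown <- character()
  for (p in df$lineage_path) {
    lv <- strsplit(p, "|", fixed = TRUE)[[1]]
    if (!lv[1] %in% SUPERFAMILIES)
      stop("lineage path must start with a superfamily: ", p)
    bad <- setdiff(lv[-1], vocab)
    unknown <- union(unknown, bad)
  }
  if (length(unknown))
    warning("unknown lineage levels: ", paste(unknown, collapse = ", "))
  structure(stats::setNames(df$lineage_path, df$element_name),
            unknown_levels = unknown)
}

#' Build a reference protein-domain database
#'
#' @param proteins named character vector of amino-acid sequences; names follow
#'   the REXdb grammar (see [parse_rexdb_name()]).
#' @param lineage_table named character vector mapping element names to
#'   lineage paths (see [read_lineage_table()]).
#' @param cage_columns optional named list: for CHD entries, the three
#'   reference-protein positions of the aromatic-cage sites.
#' @return An object of class `ltr_refdb`.
#' @export
as_refdb <- function(proteins, lineage_table, cage_columns = list()) {
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)))
  parsed <- lapply(names(proteins), parse_rexdb_name)
  entries <- data.frame(
    name = names(proteins),
    superfamily = vapply(parsed, `[[`, character(1), "superfamily"),
    domain_type = vapply(parsed, `[[`, character(1), "domain_type"),
    element_name = vapply(parsed, `[[`, character(1), "element_name"),
    stringsAsFactors = FALSE)
  bad <- setdiff(entries$domain_type, DOMAIN_TYPES)
  if (length(bad)) stop("unknown domain types: ", paste(bad, collapse = ", "))
  missing <- setdiff(entries$element_name, names(lineage_table))
  if (length(missing))
    stop("entries without lineage classification: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", proteins)))
    stop("reference proteins restricted to the 20-letter alphabet plus X")
  entries$lineage <- unname(lineage_table[entries$element_name])
  structure(list(entries = entries, proteins = proteins,
                 lineage_table = lineage_table, cage_columns = cage_columns,
                 index = new.env(parent = emptyenv())),
            class = "ltr_refdb")
}

#' Read a reference domain database from FASTA plus lineage TSV
#'
#' @param fasta_path reference protein FASTA (REXdb naming scheme).
#' @param lineage_path lineage classification TSV.
#' @param cage_path optional TSV with columns `name`, `site1`, `site2`,
#'   `site3` giving aromatic-cage positions for CHD entries.
#' @return An `ltr_refdb` object.
#' @export
read_refdb <- function(fasta_path, lineage_path, cage_path = NULL) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  proteins <- stats::setNames(toupper(as.character(aa)), names(aa))
  lt <- read_lineage_table(lineage_path)
  cage <- list()
  if (!is.null(cage_path)) {
    cg <- utils::read.delim(cage_path, sep = "\t", stringsAsFactors = FALSE)
    cage <- stats::setNames(
      lapply(seq_len(nrow(cg)), function(i) as.integer(cg[i, c("site1", "site2", "site3")])),
      cg$name)
  }
  as_refdb(proteins, lt, cage)
}

#' @export
print.ltr_refdb <- function(x, ...) {
  cat(sprintf("<ltr_refdb> %d entries, %d elements, %d lineages\n",
              nrow(x$entries), length(unique(x$entries$element_name)),
              length(unique(x$entries$lineage))))
  print(table(x$entries$domain_type))
  invisible(x)
}

#' Read a tRNA library (FASTA plus sidecar metadata TSV)
#'
#' The sidecar TSV carries columns `id`, `isoacceptor`, `anticodon_start`
#' (1-based position of the first anticodon base) and `edited_positions`
#' (empty, or `;`-separated `index:BASES` pairs giving, for each
#' post-transcriptionally edited position, the PBS bases it can pair with,
#' e.g. `35:ACT` for an inosine).
#'
#' @param fasta_path tRNA FASTA (U is mapped to T).
#' @param meta_path sidecar TSV.
#' @return A `trna_library` object (data.frame based).
#' @export
read_trna_library <- function(fasta_path, meta_path) {
  x <- Biostrings::readBStringSet(fasta_path)
  res <- chartr("U", "T", toupper(as.character(x)))
  meta <- utils::read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = c(edited_positions = "character"))
  if (!all(names(x) %in% meta$id)) stop("tRNA metadata missing for some entries")
  meta <- meta[match(names(x), meta$id), ]
  edited <- lapply(meta$edited_positions, parse_edited_positions)
  as_trna_library(data.frame(
    id = names(x), isoacceptor = meta$isoacceptor, residues = unname(res),
    anticodon_start = as.integer(meta$anticodon_start),
    stringsAsFactors = FALSE), edited)
}

parse_edited_positions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(data.frame(index = integer(), allowed = character()))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  data.frame(index = as.integer(vapply(kv, `[`, character(1), 1)),
             allowed = vapply(kv, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

as_trna_library <- function(df, edited) {
  stopifnot(all(c("id", "isoacceptor", "residues", "anticodon_start") %in% names(df)))
  bad <- df$anticodon_start > nchar(df$residues) | df$anticodon_start < 1
  if (any(bad, na.rm = TRUE)) stop("anticodon_start outside sequence")
  for (i in seq_len(nrow(df))) {
    ed <- edited[[i]]
    if (nrow(ed) && any(ed$index < 1 | ed$index > nchar(df$residues[i]) + 3))
      stop("edited position outside sequence for ", df$id[i])
  }
  df$edited <- I(edited)
  structure(df, class = c("trna_library", "data.frame"))
}

#' Write a tRNA library to FASTA plus sidecar TSV
#'
#' @param trnas a `trna_library`.
#' @param fasta_path,meta_path output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_trna_library <- function(trnas, fasta_path, meta_path) {
  write_fasta(stats::setNames(trnas$residues, trnas$id), fasta_path)
  ed <- vapply(trnas$edited, function(e) {
    if (!nrow(e)) "" else paste(sprintf("%d:%s", e$index, e$allowed), collapse = ";")
  }, character(1))
  utils::write.table(
    data.frame(id = trnas$id, isoacceptor = trnas$isoacceptor,
               anticodon_start = trnas$anticodon_start, edited_positions = ed),
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
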