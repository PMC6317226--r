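#' Pipeline configuration
#'
#' Builds the flat configuration object holding every numeric threshold used
#' across the pipeline. Defaults encode the standard screening constraints for
#' recently inserted plant LTR-retrotransposons: LTR length 100--6000 bp,
#' inter-LTR distance 1000--20,000 bp, minimum 5'/3' LTR similarity 95%,
#' TG..CA termini required, at most 10 ambiguous bases; primer-binding-site
#' rules (50 bp search window, >= 12 bp exact tRNA match, TGG anchor within
#' 0--5 bp for the fuzzy search with <= 2 differences of which <= 1 indel,
#' >= 10 bp self-primer); extra-ORF rules (>= 250 codons, tandem arrays of
#' >= 3 monomers spanning > 150 bp); and clustering rules (80% identity over
#' 90% of length, 0.90 representative-selection identity).
#'
#' Percentages are on the 0--100 scale except `rep_identity`, which follows
#' the CD-HIT style 0--1 convention of the `-c` parameter it mirrors.
#'
#' @param ... named overrides of any default value.
#' @return A named list of class `ltr_config`.
#' @examples
#' cfg <- pipeline_config(ltr_min_similarity = 90)
#' cfg$ltr_min_similarity
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ltr_min_len        = 100,
    ltr_max_len        = 6000,
    inter_ltr_min      = 1000,
    inter_ltr_max      = 20000,
    ltr_min_similarity = 95,
    require_tg_ca      = TRUE,
    max_n              = 10,
    pbs_window         = 50,
    pbs_min_exact      = 12,
    tgg_max_offset     = 5,
    fuzzy_window       = 18,
    fuzzy_max_diffs    = 2,
    fuzzy_max_indels   = 1,
    self_primer_min    = 10,
    self_primer_max    = 20,
    eorf_min_codons    = 250,
    eorf_require_atg   = TRUE,
    tandem_min_monomers = 3,
    tandem_min_span    = 150,
    tandem_max_period  = 200,
    tandem_min_agreement = 0.8,
    cluster_min_identity = 80,
    cluster_min_coverage = 90,
    rep_identity       = 0.90,
    eorf_group_evalue  = 1e-10,
    tsd_lengths        = c(4L, 5L, 6L),
    # translated search
    scan_min_score     = 80,
    scan_min_identity  = 25,
    scan_min_segment_aa = 20,
    scan_min_kmer_hits = 2,
    scan_max_refs_per_type = 4,
    chain_max_gap      = 300,
    # alignment scoring (identity thresholds above are the biological rules;
    # these are the scoring conventions they are measured under)
    dna_match          = 1,
    dna_mismatch       = -1,
    dna_gap_open       = 4,
    dna_gap_extend     = 1,
    prot_matrix        = "BLOSUM62",
    prot_gap_open      = 10,
    prot_gap_extend    = 1,
    # Karlin-Altschul constants for ungapped BLOSUM62 statistics
    ka_lambda          = 0.3176,
    ka_k               = 0.134,
    vote_confidence    = 0.5
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  validate_config(cfg)
  structure(cfg, class = "ltr_config")
}

validate_config <- function(cfg) {
  thresholds <- c("ltr_min_len", "ltr_max_len", "inter_ltr_min", "inter_ltr_max",
                  "max_n", "pbs_window", "pbs_min_exact", "tgg_max_offset",
                  "fuzzy_window", "fuzzy_max_diffs", "fuzzy_max_indels",
                  "self_primer_min", "self_primer_max", "eorf_min_codons",
                  "tandem_min_monomers", "tandem_min_span", "tandem_max_period",
                  "eorf_group_evalue", "tsd_lengths", "scan_min_score",
                  "scan_min_segment_aa", "chain_max_gap")
  if (any(unlist(cfg[thresholds]) < 0))
    stop("config thresholds must be non-negative")
  pct <- c("ltr_min_similarity", "cluster_min_identity", "cluster_min_coverage",
           "scan_min_identity")
  for (k in pct) {
    if (cfg[[k]] < 0 || cfg[[k]] > 100) stop(k, " must lie in [0, 100]")
  }
  if (cfg$rep_identity < 0 || cfg$rep_identity > 1)
    stop("rep_identity must lie in [0, 1]")
  invisible(cfg)
}

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; unknown keys are rejected.
#' Values are parsed as numeric where possible, `true`/`false` as logical, and
#' comma-separated values as vectors.
#'
#' @param path file path.
#' @return An `ltr_config` object with file values overriding the defaults.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ov <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    if (!anyNA(parsed)) {
      ov[[key]] <- parsed
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      ov[[key]] <- as.logical(toupper(parts))
    } else {
      ov[[key]] <- if (length(parts) > 1) parts else val
    }
  }
  do.call(pipeline_config, ov)
}

#' Write a configuration to a flat key=value file
#'
#' @param cfg an `ltr_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ltr_config"))
  fmt <- vapply(cfg, function(v) {
    if (is.logical(v)) paste(tolower(as.character(v)), collapse = ",")
    else paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  }, character(1))
  writeLines(paste(names(cfg), fmt, sep = " = "), path)
  invisible(path)
}

#' @export
print.ltr_config <- function(x, ...) {
  cat("<ltr_config> with", length(x), "settings\n")
  key <- c("ltr_min_len", "ltr_max_len", "inter_ltr_min", "inter_ltr_max",
           "ltr_min_similarity", "max_n", "pbs_min_exact", "eorf_min_codons",
           "cluster_min_identity", "rep_identity")
  for (k in key) cat(sprintf("  %-20s %s\n", k, paste(x[[k]], collapse = ",")))
  cat("  ... (see names(x) for the full set)\n")
  invisible(x)
}
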