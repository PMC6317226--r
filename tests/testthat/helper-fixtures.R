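# Shared fixtures, built once per test run.
fx <- local({
  cfg <- ltrclass::pipeline_config()
  refdb <- ltrclass::make_toy_refdb(n_lineages = 10, seed = 42)
  trnas <- ltrclass::make_toy_trnas(42)
  list(cfg = cfg, refdb = refdb, trnas = ltrclass::prepare_trnas(trnas),
       trnas_raw = trnas)
})

# minimal element record with a known 5' LTR, for direct PBS-detector tests
pbs_record <- function(window, ltr = NULL, ltr_len = 60) {
  if (is.null(ltr)) ltr <- paste0("TG", strrep("ACGT", (ltr_len - 4) / 4), "CA")
  seq <- paste0(ltr, window)
  rec <- list(seq = ltrclass::as_ltr_seq("pbs_test", seq),
              ltr = structure(list(five = c(1L, nchar(ltr)),
                                   three = c(nchar(seq) + 1L, nchar(seq) + nchar(ltr)),
                                   similarity = 100, termini_ok = TRUE),
                              class = "ltr_pair"))
  rec
}

# a domain-call data.frame row in the shape chain_hits emits
call_row <- function(type, start, end, lineage, score = 500,
                     strand = "+", qseq = strrep("A", (end - start + 1) / 3)) {
  sf <- strsplit(lineage, "|", fixed = TRUE)[[1]][1]
  token <- if (sf == "Ty1/copia") "Ty1" else "Ty3"
  data.frame(domain_type = type, start = start, end = end, strand = strand,
             best_ref = ltrclass::format_rexdb_name(token, type, "X_ref1"),
             lineage = lineage, superfamily = token, score = score,
             identity = 100, support = 1L, qseq = qseq,
             stringsAsFactors = FALSE)
}
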