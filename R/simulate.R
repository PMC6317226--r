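# Deterministic synthetic fixtures: toy reference database, tRNA library and
# full elements with ground-truth manifests.

# Per-lineage characteristic features used as generator defaults and mirrored
# by the shipped expectation rules: chromodomain type, aRH position, dominant
# PBS type and TSD length.
LINEAGE_FEATURES <- local({
  df <- read.table(text = "
name path chromodomain arh pbs_mode pbs_trna eorf tsd_len
CRM Ty3/gypsy|chromovirus|CRM CHDCR none full_tRNA tRNA-Met NA 5
Tekay Ty3/gypsy|chromovirus|Tekay CHD none full_tRNA tRNA-Met NA 5
Reina Ty3/gypsy|chromovirus|Reina CHD none full_tRNA tRNA-Met NA 5
Galadriel Ty3/gypsy|chromovirus|Galadriel CHD none full_tRNA tRNA-Met NA 5
Chlamyvir Ty3/gypsy|chromovirus|Chlamyvir CHD none full_tRNA tRNA-Met NA 5
Tcn1 Ty3/gypsy|chromovirus|Tcn1 CHD none self NA NA 5
Athila Ty3/gypsy|non-chromovirus|OTA|Athila none none full_tRNA tRNA-Asp eORF-3'R 5
TatI Ty3/gypsy|non-chromovirus|OTA|Tat|TatI none PROT_RT full_tRNA tRNA-Arg NA 5
TatII Ty3/gypsy|non-chromovirus|OTA|Tat|TatII none PROT_RT full_tRNA tRNA-Lys NA 5
TatIII Ty3/gypsy|non-chromovirus|OTA|Tat|TatIII none after_INT full_tRNA tRNA-Ala NA 5
Ogre Ty3/gypsy|non-chromovirus|OTA|Tat|Ogre none RH_INT fuzzy_tRNA tRNA-Arg eORF-5'F 5
Retand Ty3/gypsy|non-chromovirus|OTA|Tat|Retand none RH_INT full_tRNA tRNA-Trp eORF-5'R 5
SIRE Ty1/copia|SIRE none none full_tRNA tRNA-Met eORF-3'F 5
TAR Ty1/copia|TAR none none self NA NA 5
Bianca Ty1/copia|Bianca none none half_tRNA tRNA-Ile NA 5
Osser Ty1/copia|Osser none none half_tRNA tRNA-Met NA 4
Ale Ty1/copia|Ale none none full_tRNA tRNA-Met NA 5
Ivana Ty1/copia|Ivana none none full_tRNA tRNA-Met NA 4
", header = TRUE, stringsAsFactors = FALSE)
  df$eorf[df$eorf == "NA"] <- NA
  df$pbs_trna[df$pbs_trna == "NA"] <- NA
  df
})

# default order in which lineages are drawn into a toy reference database;
# the first nine cover both superfamilies, all PBS modes and all four eORF
# labels
DEFAULT_LINEAGE_ORDER <- c("CRM", "Tekay", "Ogre", "TatI", "Athila", "SIRE",
                           "TAR", "Bianca", "Retand", "Osser", "Tcn1",
                           "TatIII", "Ale", "Ivana", "Reina", "Galadriel",
                           "TatII", "Chlamyvir")

DOMAIN_AA_LEN <- c(GAG = 400, PROT = 130, RT = 260, RH = 130, INT = 280,
                   aRH = 130, CHD = 60, CHDCR = 60)
CAGE_COLUMNS <- c(10L, 25L, 40L)

lineage_info <- function(name) {
  row <- LINEAGE_FEATURES[LINEAGE_FEATURES$name == name, , drop = FALSE]
  if (!nrow(row)) stop("unknown fixture lineage: ", name)
  sf <- strsplit(row$path, "|", fixed = TRUE)[[1]][1]
  c(as.list(row), list(superfamily = sf,
                       sf_token = if (sf == "Ty1/copia") "Ty1" else "Ty3"))
}

lineage_domain_types <- function(info) {
  types <- if (info$sf_token == "Ty1") c("GAG", "PROT", "INT", "RT", "RH")
    else c("GAG", "PROT", "RT", "RH", "INT")
  if (info$arh == "PROT_RT") types <- append(types, "aRH", after = 2L)
  if (info$arh == "RH_INT") types <- append(types, "aRH", after = 4L)
  if (info$arh == "after_INT") types <- c(types, "aRH")
  if (info$chromodomain != "none") types <- c(types, info$chromodomain)
  types
}

mutate_protein <- function(p, frac, protect = integer()) {
  x <- chars(p)
  free <- setdiff(seq_along(x), protect)
  k <- round(frac * length(free))
  if (k > 0) {
    pos <- sample(free, k)
    x[pos] <- vapply(x[pos], function(a) sample(setdiff(AA_LETTERS, a), 1),
                     character(1))
  }
  paste(x, collapse = "")
}

mutate_dna <- function(s, k, protect = integer()) {
  x <- chars(s)
  free <- setdiff(seq_along(x), protect)
  if (k > length(free)) stop("cannot place ", k, " substitutions")
  if (k > 0) {
    pos <- sample(free, k)
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(DNA_BASES, b), 1),
                     character(1))
  }
  paste(x, collapse = "")
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(chartr("U", "T", names(gc)), gc)
})

reverse_translate <- function(prot) {
  paste(vapply(chars(prot), function(a) {
    cods <- CODON_TABLE[[a]]
    if (is.null(cods)) stop("cannot reverse-translate residue ", a)
    sample(cods, 1)
  }, character(1)), collapse = "")
}

#' Generate a toy tRNA library
#'
#' Eight isoacceptors (Met, Ile, Arg, Lys, Asp, Asn, Ala, Trp) as random
#' 72 nt sequences without the terminal CCA (which [prepare_trnas()] adds,
#' as it would for genomically predicted tRNAs), anticodon starting at
#' position 35. The tRNA-Ile entry carries an inosine annotation at the
#' first anticodon position (pairs with A, T/U and C), emulating the edited
#' half-molecule primer of Bianca elements. 3'-terminal 12-mers are checked
#' to be unique so exact PBS matches identify their tRNA unambiguously.
#'
#' @param seed integer seed.
#' @return A `trna_library`.
#' @export
make_toy_trnas <- function(seed = 1) {
  isos <- c("tRNA-Met", "tRNA-Ile", "tRNA-Arg", "tRNA-Lys",
            "tRNA-Asp", "tRNA-Asn", "tRNA-Ala", "tRNA-Trp")
  for (attempt in 0:24) {
    res <- with_seed(derive_seed(seed, attempt), {
      vapply(isos, function(i) random_dna(72), character(1))
    })
    suffixes <- substr(paste0(res, "CCA"), 64, 75)
    if (!anyDuplicated(suffixes)) break
  }
  edited <- rep(list(data.frame(index = integer(), allowed = character())),
                length(isos))
  edited[[2]] <- data.frame(index = 35L, allowed = "ACT")
  as_trna_library(data.frame(
    id = paste0(isos, "_1"), isoacceptor = isos, residues = unname(res),
    anticodon_start = 35L, stringsAsFactors = FALSE), edited)
}

#' Generate a toy reference domain database
#'
#' For each domain type one ancestral protein is drawn; each lineage
#' derives its own copy by independent substitution so that between-lineage
#' identity approximates `inter_identity`, and contributes two reference
#' entries per domain type: the lineage base and a variant at
#' `intra_identity` to it. CHD entries carry the aromatic cage (F/Y/W
#' planted at three protected columns, annotated as `cage_columns`).
#' Domain composition follows the lineage: the superfamily core, plus aRH
#' for Tat subclades and a chromodomain (CHDCR in CRM, CHD otherwise) for
#' chromovirus clades.
#'
#' @param n_lineages number of lineages (drawn from a fixed order covering
#'   both superfamilies, all PBS modes and all eORF labels within the first
#'   nine).
#' @param intra_identity,inter_identity identity targets on the 0--1 scale;
#'   requires `0 < inter_identity < intra_identity <= 1`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param lineages optional explicit character vector of lineage names
#'   (overrides `n_lineages`).
#' @return An `ltr_refdb`.
#' @export
make_toy_refdb <- function(n_lineages = 9, intra_identity = 0.95,
                           inter_identity = 0.5, seed = 1, lineages = NULL) {
  if (!(inter_identity > 0 && inter_identity < intra_identity &&
        intra_identity <= 1))
    stop("need 0 < inter_identity < intra_identity <= 1")
  if (is.null(lineages)) {
    if (n_lineages < 1 || n_lineages > length(DEFAULT_LINEAGE_ORDER))
      stop("n_lineages must be in 1..", length(DEFAULT_LINEAGE_ORDER))
    lineages <- DEFAULT_LINEAGE_ORDER[seq_len(n_lineages)]
  }
  q <- 1 - sqrt(inter_identity)   # per-copy substitution so pairs meet target
  with_seed(seed, {
    ancestors <- lapply(names(DOMAIN_AA_LEN), function(ty) {
      p <- random_protein(DOMAIN_AA_LEN[[ty]])
      if (ty == "CHD") {
        x <- chars(p)
        x[CAGE_COLUMNS] <- c("F", "Y", "W")
        p <- paste(x, collapse = "")
      }
      p
    })
    names(ancestors) <- names(DOMAIN_AA_LEN)
    proteins <- character()
    lineage_table <- character()
    cage <- list()
    for (lin in lineages) {
      info <- lineage_info(lin)
      types <- lineage_domain_types(info)
      for (rep_i in 1:2) {
        el_name <- paste0(lin, "_ref", rep_i)
        lineage_table[el_name] <- info$path
      }
      for (ty in types) {
        protect <- if (ty == "CHD") CAGE_COLUMNS else integer()
        base <- mutate_protein(ancestors[[ty]], q, protect)
        variant <- mutate_protein(base, 1 - intra_identity, protect)
        for (rep_i in 1:2) {
          nm <- format_rexdb_name(info$sf_token, ty, paste0(lin, "_ref", rep_i))
          proteins[nm] <- if (rep_i == 1) base else variant
          if (ty == "CHD") cage[[nm]] <- CAGE_COLUMNS
        }
      }
    }
    as_refdb(proteins, lineage_table, cage)
  })
}

#' Specification of one synthetic element
#'
#' @param id element id.
#' @param lineage lineage short name (one of the fixture lineages, e.g.
#'   `"CRM"`, `"Ogre"`, `"Bianca"`).
#' @param seed mandatory integer sub-seed.
#' @param pbs_mode,pbs_trna override the lineage's default PBS
#'   (`full_tRNA`, `half_tRNA`, `fuzzy_tRNA`, `self`, `none`; isoacceptor).
#' @param eorf override the lineage's default extra-ORF label
#'   (`NA` for none).
#' @param decoy_tandem also plant a tandem-repeat-borne decoy ORF that the
#'   filter must exclude.
#' @param ltr_len LTR length in bp.
#' @param target_similarity 5'/3' LTR percent identity to engineer.
#' @param tsd_len TSD length (4--6).
#' @return A list of class `element_spec`.
#' @export
element_spec <- function(id, lineage, seed, pbs_mode = NULL, pbs_trna = NULL,
                         eorf = NULL, decoy_tandem = FALSE, ltr_len = 300,
                         target_similarity = 98, tsd_len = NULL) {
  info <- lineage_info(lineage)
  structure(list(
    id = id, lineage = lineage, seed = seed,
    pbs_mode = pbs_mode %||% info$pbs_mode,
    pbs_trna = pbs_trna %||% info$pbs_trna,
    eorf = if (is.null(eorf)) info$eorf else eorf,
    decoy_tandem = decoy_tandem,
    ltr_len = ltr_len, target_similarity = target_similarity,
    tsd_len = tsd_len %||% info$tsd_len), class = "element_spec")
}

#' Build a synthetic element with ground-truth manifest
#'
#' Assembles left flank + TSD + 5' LTR (TG..CA) + PBS + optional 5' extra
#' ORFs + polyprotein cassette (domains reverse-translated in frame, in the
#' lineage's order) + optional 3' extra ORFs and tandem-repeat decoys + 3'
#' LTR (the 5' LTR mutated to the target similarity) + TSD + right flank.
#' Every planted feature is verified against the emitted sequence (and the
#' PBS and extra-ORF detectors are replayed) before returning; the rare
#' random draw in which a spurious feature collides with the ground truth
#' is rejected and rebuilt from a derived sub-seed.
#'
#' @param spec an [element_spec()].
#' @param refdb toy reference database containing the spec's lineage.
#' @param trnas a `trna_library`.
#' @param config an [pipeline_config()].
#' @return list(seq = `ltr_seq` with flanks, manifest = ground-truth list).
#' @export
build_element <- function(spec, refdb, trnas, config = pipeline_config()) {
  stopifnot(inherits(spec, "element_spec"))
  trnas <- prepare_trnas(trnas)
  last_err <- NULL
  for (attempt in 0:24) {
    res <- try(with_seed(derive_seed(spec$seed, attempt),
                         build_element_once(spec, refdb, trnas, config)),
               silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
    last_err <- res
  }
  stop("element generation failed for ", spec$id, ": ",
       attr(last_err, "condition")$message)
}

build_element_once <- function(spec, refdb, trnas, config) {
  info <- lineage_info(spec$lineage)
  types <- lineage_domain_types(info)
  L <- spec$ltr_len

  ltr5 <- paste0("TG", random_dna(L - 4), "CA")

  # --- PBS block (a self-primer plants its complement inside the 5' LTR) ---
  pbs <- build_pbs_block(spec, trnas, ltr5)
  if (!is.null(pbs$ltr_patch)) {
    at <- pbs$ltr_patch$at
    substr(ltr5, at, at + nchar(pbs$ltr_patch$seq) - 1L) <- pbs$ltr_patch$seq
  }
  n_mut <- round((1 - spec$target_similarity / 100) * L)
  ltr3 <- mutate_dna(ltr5, n_mut, protect = c(1:2, (L - 1):L))
  realized_sim <- 100 * (L - n_mut) / L

  # --- assemble with a coordinate cursor ---
  parts <- character(); cursor <- 0L
  marks <- list()
  add <- function(s, tag = NULL) {
    parts[[length(parts) + 1L]] <<- s
    iv <- c(cursor + 1L, cursor + nchar(s))
    cursor <<- iv[2]
    if (!is.null(tag)) marks[[tag]] <<- iv
    iv
  }
  add(ltr5, "ltr5")
  add(pbs$block, "pbs")
  add(random_dna(sample(40:80, 1)))

  eorf_truth <- list()
  place_eorf <- function(label, decoy = FALSE) {
    if (decoy) {
      monomer <- reverse_translate(random_protein(21))
      orf <- paste0("ATG", strrep(monomer, 13))
      block <- paste0("TAA", orf, "TAA")
    } else {
      orf <- paste0("ATG", reverse_translate(random_protein(259)))
      block <- paste0("TAA", orf, "TAA")
    }
    fwd <- substr(label, nchar(label), nchar(label)) == "F"
    ins <- if (fwd) block else revcomp(block)
    iv <- add(ins)
    # ORF interval inside the block: skip leading pin TAA, drop trailing TAA
    orf_iv <- if (fwd) c(iv[1] + 3L, iv[2] - 3L) else c(iv[1] + 3L, iv[2] - 3L)
    eorf_truth[[length(eorf_truth) + 1L]] <<- data.frame(
      label = label, start = orf_iv[1], end = orf_iv[2],
      strand = if (fwd) "+" else "-", excluded = decoy,
      stringsAsFactors = FALSE)
    add(random_dna(25))
  }

  if (!is.na(spec$eorf) && startsWith(spec$eorf, "eORF-5")) place_eorf(spec$eorf)

  # --- polyprotein cassette ---
  cass_prots <- vapply(types, function(ty) {
    nm <- format_rexdb_name(info$sf_token, ty, paste0(spec$lineage, "_ref1"))
    p <- refdb$proteins[nm]
    if (is.na(p)) stop("refdb lacks entry ", nm)
    unname(p)
  }, character(1))
  full_prot <- paste0("M", paste(cass_prots, collapse = ""))
  poly_dna <- paste0(reverse_translate(full_prot), "TAA")
  piv <- add(poly_dna, "poly")
  aa_off <- cumsum(c(1L, nchar(cass_prots)))  # aa index before each domain
  dom_truth <- data.frame(
    type = types,
    start = piv[1] + 3L * aa_off[seq_along(types)],
    end = piv[1] + 3L * aa_off[seq_along(types) + 1L] - 1L,
    stringsAsFactors = FALSE)
  add(random_dna(30))

  if (!is.na(spec$eorf) && startsWith(spec$eorf, "eORF-3")) place_eorf(spec$eorf)
  if (spec$decoy_tandem) place_eorf("eORF-3'F", decoy = TRUE)
  add(random_dna(sample(40:100, 1)))
  add(ltr3, "ltr3")
  seq <- paste(parts, collapse = "")

  # --- TSD and flanks ---
  repeat {
    tsd <- random_dna(spec$tsd_len)
    if (length(unique(chars(tsd))) > 1) break
  }
  left_flank <- paste0(random_dna(40), tsd)
  right_flank <- paste0(tsd, random_dna(40))

  el <- as_ltr_seq(spec$id, seq, left_flank, right_flank)
  d <- marks$ltr3[1] - marks$ltr5[1]
  if (d < config$inter_ltr_min || d > config$inter_ltr_max)
    stop("inter-LTR distance out of bounds: ", d)

  manifest <- list(
    id = spec$id, lineage = spec$lineage, path = info$path,
    superfamily = info$superfamily,
    ltr5 = marks$ltr5, ltr3 = marks$ltr3, ltr_len = L,
    ltr_similarity = realized_sim,
    tsd_len = spec$tsd_len, tsd_seq = tsd,
    pbs_mode = spec$pbs_mode, pbs_trna = pbs$trna_id,
    pbs_isoacceptor = pbs$isoacceptor,
    domains = dom_truth,
    arh_position = info$arh, chromodomain = info$chromodomain,
    polyprotein = c(min(dom_truth$start), max(dom_truth$end)),
    eorfs = if (length(eorf_truth)) do.call(rbind, eorf_truth) else
      data.frame(label = character(), start = integer(), end = integer(),
                 strand = character(), excluded = logical(),
                 stringsAsFactors = FALSE),
    seed = spec$seed)

  verify_element(el, manifest, trnas, config)
  list(seq = el, manifest = manifest)
}

build_pbs_block <- function(spec, trnas, ltr5) {
  mode <- spec$pbs_mode
  if (mode == "none") {
    return(list(block = random_dna(20), trna_id = NA, isoacceptor = NA))
  }
  if (mode == "self") {
    primer <- random_dna(12)
    mid <- nchar(ltr5) %/% 2
    # plant the complement inside the LTR (the builder substitutes in place)
    list(block = primer, trna_id = NA, isoacceptor = NA,
         ltr_patch = list(at = mid, seq = revcomp(primer)))
  } else {
    i <- match(spec$pbs_trna, trnas$isoacceptor)
    if (is.na(i)) stop("tRNA library lacks isoacceptor ", spec$pbs_trna)
    t <- trnas$residues[i]
    nt <- nchar(t)
    if (mode == "full_tRNA") {
      block <- revcomp(substr(t, nt - 13L, nt))      # 14 bp incl. CCA
    } else if (mode == "half_tRNA") {
      ac <- trnas$anticodon_start[i]
      e <- ac + 1L
      block <- revcomp(substr(t, e - 15L, e))        # 16 bp ending in the
      ed <- trnas$edited[[i]]                        # anticodon cleavage zone
      if (nrow(ed) && any(ed$index <= e & ed$index > e - 16L)) {
        # exercise the edited-position rule: place an allowed non-Watson-Crick
        # base opposite the first edited position
        k <- e - ed$index[1] + 1L
        bc <- chars(block)
        allowed <- setdiff(chars(ed$allowed[1]),
                           complement_base(substr(t, ed$index[1], ed$index[1])))
        bc[k] <- allowed[1]
        block <- paste(bc, collapse = "")
      }
    } else if (mode == "fuzzy_tRNA") {
      block <- revcomp(substr(t, nt - 17L, nt))      # 18 bp, starts TGG
      bc <- chars(block)
      for (k in c(6L, 11L)) bc[k] <- sample(setdiff(DNA_BASES, bc[k]), 1)
      block <- paste(bc, collapse = "")
    } else stop("unknown pbs mode: ", mode)
    list(block = block, trna_id = trnas$id[i], isoacceptor = trnas$isoacceptor[i])
  }
}

# replay the PBS and extra-ORF detectors against the ground truth; any
# disagreement aborts this draw (the caller retries with a new sub-seed)
verify_element <- function(el, manifest, trnas, config) {
  s <- el$residues
  if (substr(s, manifest$ltr5[1], manifest$ltr5[1] + 1L) != "TG" ||
      substr(s, manifest$ltr3[2] - 1L, manifest$ltr3[2]) != "CA")
    stop("termini check failed")
  rec <- list(seq = el,
              ltr = structure(list(five = manifest$ltr5, three = manifest$ltr3,
                                   similarity = manifest$ltr_similarity,
                                   termini_ok = TRUE), class = "ltr_pair"))
  pc <- call_pbs(rec, trnas, config)
  if (pc$mode != manifest$pbs_mode) stop("pbs replay: ", pc$mode)
  if (pc$mode %in% c("full_tRNA", "half_tRNA", "fuzzy_tRNA") &&
      !identical(pc$isoacceptor, manifest$pbs_isoacceptor))
    stop("pbs replay isoacceptor: ", pc$isoacceptor)
  tsd <- detect_tsd(el$left_flank, el$right_flank, config)
  if (is.null(tsd) || tsd$length != manifest$tsd_len ||
      tsd$left_seq != manifest$tsd_seq) stop("tsd replay failed")
  orfs <- find_orfs(s, config$eorf_min_codons, config$eorf_require_atg)
  if (nrow(orfs)) {
    orfs$label <- vapply(seq_len(nrow(orfs)), function(i)
      label_eorf(orfs[i, ], manifest$polyprotein), character(1))
    orfs <- filter_eorfs(orfs, find_tandem_arrays(s, config))
    got <- sort(orfs$label[!orfs$excluded & !is.na(orfs$label)])
  } else got <- character()
  truth <- manifest$eorfs
  want <- sort(truth$label[!truth$excluded])
  if (!identical(got, want)) stop("eorf replay: [", paste(got, collapse = ","),
                                  "] vs [", paste(want, collapse = ","), "]")
  if (any(truth$excluded)) {
    for (i in which(truth$excluded)) {
      hit <- which(orfs$start <= truth$start[i] & orfs$end >= truth$start[i])
      if (!length(hit) || !any(orfs$excluded[hit])) stop("decoy not excluded")
    }
  }
  invisible(TRUE)
}

#' Generate a reproducible synthetic element corpus
#'
#' Elements are apportioned across lineages by largest-remainder rounding of
#' `lineage_mix` (uniform by default), so counts are deterministic. Small
#' deterministic slices emulate corpus-level observations: every 16th
#' element carries no PBS (about the 6% of real elements with no detectable
#' primer site) and every 40th a 6 bp TSD; within the eORF-bearing OTA
#' lineages every second element additionally carries a tandem-repeat decoy
#' ORF that the filter must exclude. Per-element sub-seeds derive from the
#' master seed, so generation is reproducible element by element.
#'
#' @param n number of elements.
#' @param lineage_mix named numeric vector of lineage proportions (names are
#'   lineage short names present in `refdb`); default uniform.
#' @param seed master seed.
#' @param refdb toy reference database (default [make_toy_refdb()] with this
#'   seed).
#' @param trnas tRNA library (default [make_toy_trnas()] with this seed).
#' @param config an [pipeline_config()].
#' @return list(elements, manifests, refdb, trnas) of class `ltr_corpus`.
#' @export
make_corpus <- function(n, lineage_mix = NULL, seed = 1, refdb = NULL,
                        trnas = NULL, config = pipeline_config()) {
  stopifnot(n >= 1)
  if (is.null(refdb)) refdb <- make_toy_refdb(seed = derive_seed(seed, 0))
  if (is.null(trnas)) trnas <- make_toy_trnas(derive_seed(seed, 1))
  avail <- unique(vapply(strsplit(unname(refdb$lineage_table), "|", fixed = TRUE),
                         function(p) p[length(p)], character(1)))
  if (is.null(lineage_mix))
    lineage_mix <- stats::setNames(rep(1, length(avail)), avail)
  if (!all(names(lineage_mix) %in% avail))
    stop("lineage_mix names must be lineages of the reference database")
  w <- lineage_mix / sum(lineage_mix)
  counts <- floor(w * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(w * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  assignment <- rep(names(counts), counts)
  decoy_count <- stats::setNames(rep(0L, length(avail)), avail)
  elements <- vector("list", n)
  manifests <- vector("list", n)
  for (i in seq_len(n)) {
    lin <- assignment[i]
    args <- list(id = sprintf("elem%04d", i), lineage = lin,
                 seed = derive_seed(seed, 100 + i))
    if (i %% 16L == 0L) { args$pbs_mode <- "none"; args$pbs_trna <- NA }
    if (i %% 40L == 0L) args$tsd_len <- 6L
    info <- lineage_info(lin)
    if (!is.na(info$eorf) && info$superfamily == "Ty3/gypsy") {
      decoy_count[lin] <- decoy_count[lin] + 1L
      if (decoy_count[lin] %% 2L == 0L) args$decoy_tandem <- TRUE
    }
    spec <- do.call(element_spec, args)
    built <- build_element(spec, refdb, trnas, config)
    elements[[i]] <- built$seq
    manifests[[i]] <- built$manifest
  }
  structure(list(elements = elements, manifests = manifests,
                 refdb = refdb, trnas = trnas),
            class = "ltr_corpus")
}

#' @export
print.ltr_corpus <- function(x, ...) {
  cat(sprintf("<ltr_corpus> %d elements, %d lineages\n", length(x$elements),
              length(unique(vapply(x$manifests, `[[`, character(1), "lineage")))))
  print(table(vapply(x$manifests, `[[`, character(1), "lineage")))
  invisible(x)
}
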