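test_that("six-frame translation follows the standard code", {
  tr <- six_frame_translate("ATGGCC")
  expect_equal(tr[["+1"]], "MA")
  expect_equal(six_frame_translate("TAA")[["+1"]], "*")
  expect_equal(six_frame_translate("ATGNCC")[["+1"]], "MX")
  set.seed(41)
  s <- rand_dna(90)
  rc <- ltrclass:::revcomp(s)
  expect_equal(six_frame_translate(s)[["-1"]], six_frame_translate(rc)[["+1"]])
  expect_equal(six_frame_translate(s)[["+2"]], six_frame_translate(rc)[["-2"]])
})

test_that("an exact domain cassette is recovered at identity 100", {
  set.seed(42)
  rt_name <- grep("^Ty3-RT__Tekay_ref1$", names(fx$refdb$proteins), value = TRUE)
  rt <- fx$refdb$proteins[[rt_name]]
  dna <- paste0(rand_dna(200), "TAA", ltrclass:::reverse_translate(rt), "TAA",
                rand_dna(200))
  hits <- scan_domains(dna, fx$refdb, fx$cfg)
  rt_hits <- hits[hits$domain_type == "RT", , drop = FALSE]
  expect_gte(nrow(rt_hits), 1)
  best <- rt_hits[which.max(rt_hits$score), ]
  expect_equal(best$identity, 100)
  expect_equal(best$ref_entry, rt_name)
  expect_equal(c(best$start, best$end), c(204L, 203L + 3L * nchar(rt)))
  # coordinate mapping is involutive: the hit interval translates back to
  # the reference protein
  aa <- six_frame_translate(substr(dna, best$start, best$end))[["+1"]]
  expect_equal(aa, rt)
})

test_that("a frameshift splits a domain into chainable adjacent-frame hits", {
  set.seed(43)
  rt_name <- "Ty3-RT__Tekay_ref1"
  rt <- fx$refdb$proteins[[rt_name]]
  cass <- ltrclass:::reverse_translate(rt)
  mid <- 390   # delete one base a third of the way in
  dna <- paste0(rand_dna(150), "TAA", substr(cass, 1, mid),
                substr(cass, mid + 2, nchar(cass)), "TAA", rand_dna(150))
  hits <- scan_domains(dna, fx$refdb, fx$cfg)
  rt_hits <- hits[hits$domain_type == "RT" & hits$ref_entry == rt_name, ]
  expect_equal(nrow(rt_hits), 2)
  expect_length(unique(rt_hits$frame), 2)
  calls <- chain_hits(hits, fx$cfg)
  rt_calls <- calls[calls$domain_type == "RT", ]
  expect_equal(nrow(rt_calls), 1)
  expect_equal(rt_calls$support, 2)
  # chained call spans the constituents and aggregates their scores
  expect_lte(min(rt_hits$start), rt_calls$start)
  expect_gte(rt_calls$end, max(rt_hits$end))
  expect_gte(rt_calls$score, max(rt_hits$score))
})

test_that("random DNA produces no domain hits", {
  set.seed(44)
  expect_equal(nrow(scan_domains(rand_dna(3000), fx$refdb, fx$cfg)), 0)
})

test_that("chaining resolves overlaps by score and keeps distant duplicates", {
  h <- function(type, start, end, frame, score, rstart = 1) {
    data.frame(ref_entry = paste0("Ty3-", type, "__Tekay_ref1"),
               domain_type = type, lineage = "Ty3/gypsy|chromovirus|Tekay",
               superfamily = "Ty3", start = start, end = end, strand = "+",
               frame = frame, score = score, identity = 90,
               rstart = rstart, rend = rstart + (end - start) %/% 3,
               qseq = strrep("A", (end - start + 1) %/% 3),
               stringsAsFactors = FALSE)
  }
  # RH overlapping a higher-scoring RT by ~90% is dropped
  calls <- chain_hits(rbind(h("RT", 1000, 1780, 1, 900),
                            h("RH", 1050, 1700, 1, 300)), fx$cfg)
  expect_equal(calls$domain_type, "RT")
  # two same-type hits far apart stay separate and flag duplication
  calls2 <- chain_hits(rbind(h("RT", 1000, 1780, 1, 900, rstart = 1),
                             h("RT", 3000, 3780, 1, 880, rstart = 1)), fx$cfg)
  expect_equal(nrow(calls2), 2)
  arch <- validate_architecture(calls2)
  expect_true("duplicate_domain" %in% arch$flags)
})

test_that("architecture templates assign superfamilies and aRH position", {
  crm <- "Ty3/gypsy|chromovirus|CRM"
  ty1 <- "Ty1/copia|SIRE"
  # Ty1/copia order without GAG
  a1 <- validate_architecture(rbind(
    call_row("PROT", 100, 489, ty1), call_row("INT", 500, 1339, ty1),
    call_row("RT", 1350, 2129, ty1), call_row("RH", 2140, 2529, ty1)))
  expect_equal(a1$superfamily, "Ty1/copia")
  expect_true("missing_GAG" %in% a1$flags)
  expect_false("bad_order" %in% a1$flags)
  # Ty3/gypsy order with aRH between RH and INT
  ogre <- "Ty3/gypsy|non-chromovirus|OTA|Tat|Ogre"
  a2 <- validate_architecture(rbind(
    call_row("GAG", 100, 1299, ogre), call_row("PROT", 1300, 1689, ogre),
    call_row("RT", 1700, 2479, ogre), call_row("RH", 2490, 2879, ogre),
    call_row("aRH", 2890, 3279, ogre), call_row("INT", 3290, 4129, ogre)))
  expect_equal(a2$superfamily, "Ty3/gypsy")
  expect_equal(a2$arh_position, "RH_INT")
  expect_length(setdiff(a2$flags, character()), 0)
  # swapped core order matches no template
  a3 <- validate_architecture(rbind(
    call_row("GAG", 100, 1299, ty1), call_row("PROT", 1300, 1689, ty1),
    call_row("RT", 1700, 2479, ty1), call_row("INT", 2490, 3329, ty1),
    call_row("RH", 3340, 3729, ty1)))
  expect_equal(a3$superfamily, "undetermined")
  expect_true("bad_order" %in% a3$flags)
  # no calls at all
  a4 <- validate_architecture(NULL)
  expect_equal(a4$superfamily, "undetermined")
  expect_true("no_polyprotein" %in% a4$flags)
})

test_that("mixed-superfamily best hits raise the chimera flag", {
  crm <- "Ty3/gypsy|chromovirus|CRM"
  calls <- rbind(call_row("GAG", 100, 1299, crm),
                 call_row("PROT", 1300, 1689, crm),
                 call_row("RT", 1700, 2479, "Ty1/copia|SIRE"),
                 call_row("RH", 2490, 2879, crm),
                 call_row("INT", 2890, 3729, crm))
  expect_true("chimera" %in% validate_architecture(calls)$flags)
})
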