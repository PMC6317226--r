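rc <- ltrclass:::revcomp

test_that("tRNA preparation appends exactly one CCA and is idempotent", {
  lib <- fx$trnas_raw
  prepped <- prepare_trnas(lib)
  expect_true(all(endsWith(prepped$residues, "CCA")))
  again <- prepare_trnas(prepped)
  expect_identical(again$residues, prepped$residues)
  expect_identical(prepped$anticodon_start, lib$anticodon_start)
  ends_ggt <- lib$residues[1]
  expect_equal(prepare_trnas(lib)$residues[1], paste0(ends_ggt, "CCA"))
})

test_that("exact PBS requires twelve matched bases including the tRNA 3' end", {
  set.seed(51)
  trnas <- fx$trnas
  t1 <- trnas$residues[trnas$isoacceptor == "tRNA-Met"]
  nt <- nchar(t1)
  stop15 <- setdiff(c("A", "C", "G", "T"),
                    ltrclass:::complement_base(substr(t1, nt - 14, nt - 14)))[1]
  win14 <- paste0(rc(substr(t1, nt - 13, nt)), stop15, rand_dna(35))
  call <- find_exact_pbs(pbs_record(win14), trnas, fx$cfg)
  expect_equal(call$mode, "full_tRNA")
  expect_equal(call$isoacceptor, "tRNA-Met")
  expect_equal(call$match_len, 14)
  expect_equal(call$offset, 0)
  # eleven matched bases are one short
  frag11 <- rc(substr(t1, nt - 10, nt))
  bad_next <- setdiff(c("A", "C", "G", "T"),
                      ltrclass:::complement_base(substr(t1, nt - 11, nt - 11)))[1]
  win11 <- paste0(frag11, bad_next, rand_dna(30))
  expect_null(find_exact_pbs(pbs_record(win11), trnas, fx$cfg))
})

test_that("ties between equally long matches go to the smaller offset", {
  trnas <- fx$trnas
  tA <- trnas$residues[1]; tB <- trnas$residues[3]
  pbsA <- rc(substr(tA, nchar(tA) - 12, nchar(tA)))   # 13 bp each
  pbsB <- rc(substr(tB, nchar(tB) - 12, nchar(tB)))
  # bases that stop either match from extending past 13 bp
  stopB <- setdiff(c("A", "C", "G", "T"),
                   ltrclass:::complement_base(substr(tB, nchar(tB) - 13, nchar(tB) - 13)))[1]
  stopA <- setdiff(c("A", "C", "G", "T"),
                   ltrclass:::complement_base(substr(tA, nchar(tA) - 13, nchar(tA) - 13)))[1]
  set.seed(59)
  win <- paste0(pbsB, stopB, pbsA, stopA, rand_dna(16))
  call <- find_exact_pbs(pbs_record(win), trnas, fx$cfg)
  expect_equal(call$match_len, 13)
  expect_equal(call$offset, 0)
  expect_equal(call$isoacceptor, trnas$isoacceptor[3])
})

test_that("fuzzy PBS accepts two differences with at most one indel", {
  trnas <- fx$trnas
  t1 <- trnas$residues[trnas$isoacceptor == "tRNA-Arg"]
  nt <- nchar(t1)
  base <- rc(substr(t1, nt - 17, nt))   # 18 bp starting TGG
  expect_true(startsWith(base, "TGG"))
  two_subs <- base
  for (k in c(6, 11)) {
    old <- substr(two_subs, k, k)
    substr(two_subs, k, k) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  set.seed(52)
  call <- find_fuzzy_pbs(pbs_record(paste0(two_subs, rand_dna(30))), trnas, fx$cfg)
  expect_equal(call$mode, "fuzzy_tRNA")
  expect_equal(call$isoacceptor, "tRNA-Arg")
  expect_equal(call$diffs, 2)
  expect_equal(call$indels, 0)
  # one substitution plus one inserted base
  ins <- paste0(substr(base, 1, 8), "A", substr(base, 9, 17))
  substr(ins, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(ins, 5, 5))[1]
  call2 <- find_fuzzy_pbs(pbs_record(paste0(ins, rand_dna(30))), trnas, fx$cfg)
  expect_equal(call2$mode, "fuzzy_tRNA")
  expect_equal(call2$diffs + call2$indels, 2)
  expect_lte(call2$indels, 1)
  # three substitutions exceed the budget
  three <- base
  for (k in c(6, 11, 15)) {
    substr(three, k, k) <- setdiff(c("A", "C", "G", "T"), substr(three, k, k))[1]
  }
  expect_null(find_fuzzy_pbs(pbs_record(paste0(three, rand_dna(30))), trnas, fx$cfg))
})

test_that("half-tRNA PBS must end within the anticodon cleavage window", {
  set.seed(53)
  trnas <- fx$trnas
  i <- which(trnas$isoacceptor == "tRNA-Met")
  t1 <- trnas$residues[i]; ac <- trnas$anticodon_start[i]
  e <- ac + 1
  win <- paste0(rc(substr(t1, e - 15, e)), rand_dna(30))
  call <- find_half_trna_pbs(pbs_record(win), trnas, fx$cfg)
  expect_equal(call$mode, "half_tRNA")
  expect_equal(call$isoacceptor, "tRNA-Met")
  expect_gte(call$match_len, 12)
  # a 16 bp match ending 10 bp before the anticodon window is rejected
  e_far <- ac - 13
  win_far <- paste0(rc(substr(t1, e_far - 15, e_far)), rand_dna(30))
  expect_null(find_half_trna_pbs(pbs_record(win_far), trnas, fx$cfg))
})

test_that("edited tRNA positions pair with their annotated bases", {
  trnas <- fx$trnas
  i <- which(trnas$isoacceptor == "tRNA-Ile")
  t1 <- trnas$residues[i]; ac <- trnas$anticodon_start[i]
  e <- ac + 1
  block <- rc(substr(t1, e - 15, e))
  k <- e - ac + 1    # pattern position opposite the inosine
  wc <- ltrclass:::complement_base(substr(t1, ac, ac))
  alt <- setdiff(c("A", "C", "T"), wc)[1]   # allowed but non-Watson-Crick
  substr(block, k, k) <- alt
  set.seed(54)
  tail30 <- rand_dna(30)
  call <- find_half_trna_pbs(pbs_record(paste0(block, tail30)), trnas, fx$cfg)
  expect_equal(call$mode, "half_tRNA")
  expect_equal(call$isoacceptor, "tRNA-Ile")
  expect_gte(call$match_len, 16)
  # a base outside the annotated pairing set breaks the anchored match;
  # only a shorter, offset suffix alignment can remain
  substr(block, k, k) <- "G"
  call2 <- find_half_trna_pbs(pbs_record(paste0(block, tail30)), trnas, fx$cfg)
  expect_true(is.null(call2) || call2$match_len < 16)
})

test_that("self-priming needs ten complementary bases inside the 5' LTR", {
  set.seed(55)
  primer12 <- rand_dna(12)
  ltr <- paste0("TG", rand_dna(100), rc(primer12), rand_dna(100), "CA")
  rec <- pbs_record(paste0(primer12, rand_dna(30)), ltr = ltr)
  call <- find_self_primer(rec, fx$cfg)
  expect_equal(call$mode, "self")
  expect_gte(call$match_len, 12)
  # nine complementary bases are not enough
  primer9 <- rand_dna(9)
  ltr9 <- paste0("TG", rand_dna(100), rc(primer9), rand_dna(100), "CA")
  bad_tail <- rand_dna(31)
  rec9 <- pbs_record(paste0(primer9, bad_tail), ltr = ltr9)
  got <- find_self_primer(rec9, fx$cfg)
  if (!is.null(got)) expect_gte(got$match_len, 10)   # only a chance >=10 hit
  # complement downstream of the LTR (not inside it) does not count
  recd <- pbs_record(paste0(primer12, rc(primer12), rand_dna(20)))
  expect_null(find_self_primer(recd, fx$cfg))
})

test_that("detector precedence is full > half > fuzzy > self > none", {
  trnas <- fx$trnas
  t1 <- trnas$residues[trnas$isoacceptor == "tRNA-Met"]
  nt <- nchar(t1)
  set.seed(56)
  primer <- rand_dna(12)
  ltr <- paste0("TG", rand_dna(80), rc(primer), rand_dna(80), "CA")
  # both a full-tRNA match and a self-primer are present: full wins
  win_both <- paste0(rc(substr(t1, nt - 13, nt)), primer, rand_dna(20))
  both <- call_pbs(pbs_record(win_both, ltr = ltr), trnas, fx$cfg)
  expect_equal(both$mode, "full_tRNA")
  # self only
  self_only <- call_pbs(pbs_record(paste0(primer, rand_dna(30)), ltr = ltr),
                        trnas, fx$cfg)
  expect_equal(self_only$mode, "self")
  # nothing at all
  none <- call_pbs(pbs_record(strrep("A", 50)), trnas, fx$cfg)
  expect_equal(none$mode, "none")
  expect_error(find_exact_pbs(list(seq = as_ltr_seq("x", "ACGT"), ltr = NULL),
                              trnas, fx$cfg), "requires 5' LTR")
})

test_that("PBS intervals are translation-equivariant with the LTR annotation", {
  trnas <- fx$trnas
  t1 <- trnas$residues[trnas$isoacceptor == "tRNA-Met"]
  nt <- nchar(t1)
  set.seed(57)
  win <- paste0(rc(substr(t1, nt - 13, nt)), rand_dna(36))
  rec <- pbs_record(win)
  base_call <- find_exact_pbs(rec, trnas, fx$cfg)
  k <- 17L
  shifted <- rec
  shifted$seq <- as_ltr_seq("shifted", paste0(rand_dna(k), rec$seq$residues))
  shifted$ltr$five <- rec$ltr$five + k
  shift_call <- find_exact_pbs(shifted, trnas, fx$cfg)
  expect_equal(shift_call$start, base_call$start + k)
  expect_equal(shift_call$end, base_call$end + k)
  expect_equal(shift_call$offset, base_call$offset)
})

test_that("generated PBS modes round-trip through call_pbs", {
  set.seed(58)
  cases <- list(
    list(lineage = "Tekay", mode = "full_tRNA", iso = "tRNA-Met"),
    list(lineage = "Osser", mode = "half_tRNA", iso = "tRNA-Met"),
    list(lineage = "Bianca", mode = "half_tRNA", iso = "tRNA-Ile"),
    list(lineage = "Ogre", mode = "fuzzy_tRNA", iso = "tRNA-Arg"),
    list(lineage = "TAR", mode = "self", iso = NULL),
    list(lineage = "Tekay", mode = "none", iso = NULL, over = TRUE))
  for (cs in cases) {
    for (k in 1:8) {
      args <- list(id = paste0(cs$lineage, cs$mode, k), lineage = cs$lineage,
                   seed = k * 37L)
      if (isTRUE(cs$over)) { args$pbs_mode <- "none"; args$pbs_trna <- NA }
      b <- build_element(do.call(element_spec, args),
                         fx$refdb, fx$trnas_raw, fx$cfg)
      rec <- list(seq = b$seq,
                  ltr = structure(list(five = b$manifest$ltr5,
                                       three = b$manifest$ltr3,
                                       similarity = 98, termini_ok = TRUE),
                                  class = "ltr_pair"))
      call <- call_pbs(rec, fx$trnas, fx$cfg)
      expect_equal(call$mode, cs$mode, info = paste(cs$lineage, k))
      if (!is.null(cs$iso)) expect_equal(call$isoacceptor, cs$iso)
      expect_lte(call$diffs + call$indels, fx$cfg$fuzzy_max_diffs)
      expect_lte(call$indels, fx$cfg$fuzzy_max_indels)
    }
  }
})
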