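make_orf_dna <- function(n_codons) {
  paste0("ATG", ltrclass:::reverse_translate(rand_prot(n_codons - 1)), "TAA")
}

test_that("ORF detection honours the 250-codon minimum exactly", {
  set.seed(61)
  s250 <- paste0(rand_dna(30), "TAA", make_orf_dna(250), rand_dna(30))
  orfs <- find_orfs(s250, 250)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$codons, 250)
  expect_equal(orfs$strand, "+")
  s249 <- paste0(rand_dna(30), "TAA", make_orf_dna(249), rand_dna(30))
  expect_equal(nrow(find_orfs(s249, 250)), 0)
})

test_that("reverse-strand ORFs come back in forward coordinates", {
  set.seed(62)
  orf <- make_orf_dna(260)
  lead <- rand_dna(33)
  s <- paste0(lead, "TTA", ltrclass:::revcomp(orf), "TTA", rand_dna(30))
  orfs <- find_orfs(s, 250)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$strand, "-")
  # interval excludes the stop codon; the ATG sits at the 3' end on the
  # forward strand
  expect_equal(orfs$end, nchar(lead) + 3 + nchar(orf))
  expect_equal(substr(s, orfs$end - 2, orfs$end), ltrclass:::revcomp("ATG"))
})

test_that("extra ORFs are labeled by side and orientation", {
  poly <- c(2000L, 6000L)
  expect_equal(label_eorf(list(start = 6500, end = 7400, strand = "+"), poly),
               "eORF-3'F")
  expect_equal(label_eorf(list(start = 500, end = 1400, strand = "-"), poly),
               "eORF-5'R")
  expect_true(is.na(label_eorf(list(start = 5999, end = 6900, strand = "+"), poly)))
  expect_error(label_eorf(list(start = 1, end = 2, strand = "+"), NULL),
               "cannot label")
})

test_that("tandem arrays report the fundamental period and copy number", {
  arr <- find_tandem_arrays(strrep("ACGTT", 40), fx$cfg)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$period, 5)
  expect_equal(arr$copies, 40)
  expect_equal(arr$period, autocorrelation_period(strrep("ACGTT", 40)))
  # two copies / 10 bp: below every threshold
  expect_equal(nrow(find_tandem_arrays(strrep("ACGTT", 2), fx$cfg)), 0)
  # seeded random sequence has no qualifying array
  set.seed(63)
  expect_equal(nrow(find_tandem_arrays(rand_dna(1000), fx$cfg)), 0)
})

test_that("the monomer/span thresholds separate 2x100 from 3x60 arrays", {
  set.seed(64)
  mono100 <- rand_dna(100)
  expect_equal(nrow(find_tandem_arrays(paste0(rand_dna(40), strrep(mono100, 2),
                                              rand_dna(40)), fx$cfg)), 0)
  mono60 <- rand_dna(60)
  arr <- find_tandem_arrays(paste0(rand_dna(40), strrep(mono60, 3),
                                   rand_dna(40)), fx$cfg)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$period, 60)
  expect_gte(arr$copies, 3)
  expect_gt(arr$end - arr$start + 1, 150)
})

test_that("eORFs over tandem arrays are excluded at half-overlap", {
  orfs <- data.frame(start = c(100L, 1000L), end = c(400L, 1900L),
                     strand = "+", codons = c(100L, 300L),
                     label = c("eORF-5'F", "eORF-3'F"),
                     stringsAsFactors = FALSE)
  arrays <- data.frame(start = 90L, end = 420L, period = 60L, copies = 5.5,
                       consensus = "X", stringsAsFactors = FALSE)
  out <- filter_eorfs(orfs, arrays)
  expect_true(out$excluded[1])
  expect_equal(out$reason[1], "tandem_repeat")
  expect_false(out$excluded[2])
  # 10% overlap is retained
  arrays2 <- data.frame(start = 380L, end = 410L, period = 10L, copies = 3.1,
                        consensus = "X", stringsAsFactors = FALSE)
  expect_false(any(filter_eorfs(orfs, arrays2)$excluded))
  expect_false(any(filter_eorfs(orfs, NULL)$excluded))
})

test_that("shuffling a tandem region away removes the exclusions", {
  set.seed(65)
  mono <- rand_dna(60)
  tandem_part <- strrep(mono, 5)
  shuffled <- paste(sample(strsplit(tandem_part, "")[[1]]), collapse = "")
  orfs <- data.frame(start = 41L, end = 340L, strand = "+", codons = 100L,
                     label = "eORF-5'F", stringsAsFactors = FALSE)
  with_arr <- filter_eorfs(orfs, find_tandem_arrays(
    paste0(rand_dna(40), tandem_part, rand_dna(40)), fx$cfg))
  expect_true(with_arr$excluded[1])
  without <- filter_eorfs(orfs, find_tandem_arrays(
    paste0(rand_dna(40), shuffled, rand_dna(40)), fx$cfg))
  expect_false(without$excluded[1])
})

test_that("eORF proteins group by connected components of significant pairs", {
  set.seed(66)
  p <- rand_prot(300)
  prots <- c(A = p, B = p, C = rand_prot(300))
  g <- group_eorf_proteins(prots, config = fx$cfg)
  expect_equal(unname(g["A"]), unname(g["B"]))
  expect_false(g[["C"]] == g[["A"]])
  expect_length(group_eorf_proteins(character(), config = fx$cfg), 0)
  # a zero threshold separates everything
  g0 <- group_eorf_proteins(prots, evalue_threshold = 0, config = fx$cfg)
  expect_length(unique(g0), 3)
  # grouping is a partition and order-invariant
  g2 <- group_eorf_proteins(prots[c(3, 1, 2)], config = fx$cfg)
  expect_equal(g2[["A"]] == g2[["B"]], TRUE)
  expect_false(g2[["C"]] == g2[["A"]])
})
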