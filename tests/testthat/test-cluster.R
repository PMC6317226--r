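test_that("domain concatenation is fixed-order PROT,RT,RH,INT", {
  set.seed(81)
  b <- build_element(element_spec("cc1", "Tekay", seed = 3), fx$refdb,
                     fx$trnas_raw, fx$cfg)
  el <- annotate_element(b$seq, fx$refdb, fx$trnas, fx$cfg)
  cat_prot <- concat_domains(el)
  lens <- vapply(c("PROT", "RT", "RH", "INT"), function(ty)
    nchar(el$architecture$calls$qseq[el$architecture$calls$domain_type == ty]),
    numeric(1))
  expect_equal(nchar(cat_prot), sum(lens))
  expect_true(startsWith(cat_prot,
    el$architecture$calls$qseq[el$architecture$calls$domain_type == "PROT"]))
  # a Ty1 element (different genomic order) concatenates identically by type
  b1 <- build_element(element_spec("cc2", "SIRE", seed = 4), fx$refdb,
                      fx$trnas_raw, fx$cfg)
  el1 <- annotate_element(b1$seq, fx$refdb, fx$trnas, fx$cfg)
  expect_true(startsWith(concat_domains(el1),
    el1$architecture$calls$qseq[el1$architecture$calls$domain_type == "PROT"]))
  # missing domain: warn and skip
  el_miss <- el
  el_miss$architecture$calls <-
    el$architecture$calls[el$architecture$calls$domain_type != "RH", ]
  expect_warning(out <- concat_domains(el_miss), "RH")
  expect_true(is.na(out))
})

test_that("identity clustering respects the 80%/90% thresholds", {
  set.seed(82)
  p <- rand_prot(300)
  prots <- c(a = p, b = p)
  expect_equal(unname(cluster_by_identity(prots, fx$cfg)), c(1L, 1L))
  # exactly 80% identity joins, 79% does not
  prots80 <- c(a = p, b = mut_even_prot(p, 60))
  expect_equal(length(unique(cluster_by_identity(prots80, fx$cfg))), 1)
  prots79 <- c(a = p, b = mut_even_prot(p, 63))
  expect_equal(length(unique(cluster_by_identity(prots79, fx$cfg))), 2)
  # high identity over only a third of the length fails the span rule
  partial <- paste0(substr(p, 1, 100), rand_prot(200))
  mixed <- c(a = p, b = partial)
  expect_equal(length(unique(cluster_by_identity(mixed, fx$cfg))), 2)
})

test_that("clusters are transitive closures and order-invariant", {
  set.seed(83)
  a <- rand_prot(300)
  b <- mut_even_prot(a, 30)        # 90% to a
  c_ <- mut_even_prot(b, 30)       # 90% to b, ~81-90% to a
  d <- rand_prot(300)
  prots <- c(A = a, B = b, C = c_, D = d)
  cl <- cluster_by_identity(prots, fx$cfg)
  expect_equal(length(unique(cl[c("A", "B", "C")])), 1)
  expect_false(cl[["D"]] == cl[["A"]])
  cl2 <- cluster_by_identity(prots[c("D", "C", "A", "B")], fx$cfg)
  grp <- function(cl, ids) unname(cl[ids[1]] == cl[ids[2]])
  expect_true(grp(cl2, c("A", "B")) && grp(cl2, c("B", "C")))
  expect_false(grp(cl2, c("A", "D")))
})

test_that("representative selection follows the greedy seed rule", {
  set.seed(84)
  p <- rand_prot(200)
  expect_equal(select_representative("only", c(only = p), fx$cfg), "only")
  near <- c(s1 = paste0(p, "AA"), s2 = paste0(p, "A"), s3 = p)
  expect_equal(select_representative(names(near), near, fx$cfg), "s1")
  # two sub-groups: three near-identical long vs two unrelated short
  q <- rand_prot(150)
  prots <- c(x1 = paste0(p, "AAA"), x2 = paste0(p, "AA"), x3 = p,
             y1 = paste0(q, "A"), y2 = q)
  expect_equal(select_representative(names(prots), prots, fx$cfg), "x1")
})

test_that("observed distances use pairwise gap deletion", {
  aln <- c(r1 = "ACGTACGTAC", r2 = "ACGTACGTAC")
  d <- observed_distance_matrix(aln)
  expect_equal(unname(d[1, 2]), 0)
  expect_equal(diag(d), c(r1 = 0, r2 = 0))
  d2 <- observed_distance_matrix(c(x = "AC-T", y = "ACGT"))
  expect_equal(unname(d2["x", "y"]), 0)
  d3 <- observed_distance_matrix(c(x = "AAAAAAAAAA", y = "AAAAAAAACC"))
  expect_equal(unname(d3["x", "y"]), 0.2)
  expect_error(observed_distance_matrix(c(a = "ACG", b = "AC")), "ragged")
  expect_error(observed_distance_matrix(c(a = "--A", b = "A--")),
               "no comparable columns")
})

test_that("neighbor joining is exact on additive matrices", {
  m <- additive_matrix_4()
  nwk <- nj_tree(m)
  pl <- newick_path_lengths(nwk)
  expect_equal(max(abs(pl - m[rownames(pl), colnames(pl)])), 0,
               tolerance = 1e-9)
  # topology matches classic NJ (ape) on the same matrix
  skip_if_not_installed("ape")
  ours <- ape::unroot(ape::read.tree(text = nwk))
  theirs <- ape::unroot(ape::nj(m))
  expect_equal(ape::dist.topo(ours, theirs)[1], 0)
})

test_that("equidistant taxa give a star-like tree and label permutation only relabels", {
  m <- matrix(0.6, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(m) <- 0
  pl <- newick_path_lengths(nj_tree(m))
  expect_equal(max(abs(pl - m[rownames(pl), colnames(pl)])), 0,
               tolerance = 1e-9)
  skip_if_not_installed("ape")
  m4 <- additive_matrix_4()
  perm <- c("C", "A", "D", "B")
  t1 <- ape::unroot(ape::read.tree(text = nj_tree(m4)))
  t2 <- ape::unroot(ape::read.tree(text = nj_tree(m4[perm, perm])))
  expect_equal(ape::dist.topo(t1, t2)[1], 0)
  expect_error(nj_tree(m4[1:2, 1:2]), "at least 3")
})

test_that("two divergent families produce a bimodal distance distribution", {
  set.seed(85)
  anc1 <- rand_prot(200)
  anc2 <- rand_prot(200)
  fam1 <- vapply(1:5, function(i) mut_rand_prot(anc1, 20), "")   # ~90% to anc1
  fam2 <- vapply(1:5, function(i) mut_rand_prot(anc2, 20), "")
  aln <- c(fam1, fam2)
  names(aln) <- paste0("s", 1:10)
  d <- observed_distance_matrix(aln)
  fam <- rep(1:2, each = 5)
  intra <- d[outer(fam, fam, "==") & upper.tri(d)]
  inter <- d[outer(fam, fam, "!=") & upper.tri(d)]
  expect_lt(max(intra), 0.35)
  expect_gt(min(inter), max(intra) + 0.1)   # an empty band separates modes
})
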