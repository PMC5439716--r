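test_that("binary encoding produces one presence column per observed allele", {
  tab <- gt_from_strings(matrix(c("155/155", "155/158"), nrow = 1))
  b <- to_binary(tab)
  expect_equal(colnames(b), c("L01:155", "L01:158"))
  expect_equal(unname(b["A01", ]), c(1L, 0L))
  expect_equal(unname(b["A02", ]), c(1L, 1L))

  tab2 <- gt_from_strings(rbind(c("155/158", "."), c("200/200", "203/206")))
  b2 <- to_binary(tab2)
  expect_equal(unname(rowSums(b2[, attr(b2, "loci") == "L01", drop = FALSE])),
               c(2, 0))
  mb <- attr(b2, "missing_blocks")
  expect_equal(mb$accession, "A02")
  expect_equal(mb$locus, "L01")

  # column count equals the panel's total allele count
  gt <- make_genotype_table(n_loci = 10, n_accessions = 25, seed = 60)
  st <- diversity_stats(gt$table, f_null = FALSE)
  expect_equal(ncol(to_binary(gt$table)), sum(st$n_alleles))
})

test_that("distances satisfy metric basics and hand-computed toy values", {
  tab <- gt_from_strings(rbind(c("100/103", "100/103", "106/109"),
                               c("200/200", "200/203", "206/206")))
  b <- to_binary(tab)
  for (m in c("simple_matching", "dice", "shared_allele")) {
    d <- distance_matrix(b, method = m)
    expect_equal(unname(diag(d)), rep(0, 3))
    expect_equal(d, t(d))
    expect_true(all(d >= 0))
  }
  # A01 vs A02: L1 shares both alleles (dice 1), L2 shares 200: 2*1/(1+2)
  d_sa <- distance_matrix(b, method = "shared_allele")
  expect_equal(d_sa["A01", "A02"], 1 - mean(c(1, 2 / 3)))
  # A01 vs A03 disjoint everywhere
  expect_equal(d_sa["A01", "A03"], 1)
  expect_equal(distance_matrix(b, method = "dice")["A01", "A03"], 1)
  # simple matching A01 vs A02: columns 100,103,106,109,200,203,206
  # A01: 1 1 0 0 | 1 0 0 ; A02: 1 1 0 0 | 1 1 0 -> 1 mismatch of 7
  expect_equal(distance_matrix(b, method = "simple_matching")["A01", "A02"], 1 / 7)
  expect_error(distance_matrix(b, method = "nope"))
})

test_that("identical accessions are at distance zero for all methods", {
  tab <- gt_from_strings(rbind(c("100/103", "100/103"), c("200/203", "200/203")))
  b <- to_binary(tab)
  for (m in c("simple_matching", "dice", "shared_allele")) {
    expect_equal(distance_matrix(b, m)["A01", "A02"], 0)
  }
})

test_that("NJ reconstructs additive distances exactly", {
  set.seed(61)
  for (r in 1:5) {
    tree <- ape::rtree(6, br = function(n) stats::runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(tree)
    nj <- neighbor_joining(d)
    d2 <- ape::cophenetic.phylo(nj)
    expect_lt(max(abs(d2[rownames(d), colnames(d)] - d)), 1e-9)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), "3 taxa")
})

test_that("3-taxon NJ has the closed-form star branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (3 + 5 - 6) / 2)
  expect_equal(unname(bl["b"]), (3 + 6 - 5) / 2)
  expect_equal(unname(bl["c"]), (5 + 6 - 3) / 2)
})

test_that("tree builders are invariant to taxon input order", {
  set.seed(62)
  tree <- ape::rcoal(7)
  d <- ape::cophenetic.phylo(tree)
  perm <- sample(rownames(d))
  dp <- d[perm, perm]
  expect_equal(phangorn::RF.dist(neighbor_joining(d), neighbor_joining(dp)), 0)
  expect_equal(phangorn::RF.dist(upgma_tree(d), upgma_tree(dp),
                                 rooted = TRUE), 0)
})

test_that("UPGMA recovers ultrametric trees and balances two taxa", {
  set.seed(63)
  for (r in 1:5) {
    tree <- ape::rcoal(6)
    d <- ape::cophenetic.phylo(tree)
    up <- upgma_tree(d)
    expect_true(ape::is.ultrametric(up))
    expect_equal(phangorn::RF.dist(up, tree, rooted = TRUE), 0)
  }
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  up2 <- upgma_tree(d2)
  expect_equal(unname(up2$edge.length), c(1, 1))
})

test_that("Newick output reparses to an isomorphic tree", {
  gt <- make_genotype_table(n_loci = 15, n_accessions = 12, seed = 64)
  nwk <- tempfile(fileext = ".nwk")
  tr <- genotype_tree(gt$table, method = "nj", newick_path = nwk)
  back <- ape::read.tree(nwk)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_setequal(back$tip.label, gt$table$accessions)
  # negative-branch clamping is available
  d <- distance_matrix(to_binary(gt$table))
  tr2 <- neighbor_joining(d, clamp = TRUE)
  expect_true(all(tr2$edge.length >= 0))
})
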