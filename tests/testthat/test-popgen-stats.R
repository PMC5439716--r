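test_that("allele frequencies count homozygotes twice and heterozygotes once", {
  tab <- gt_from_strings(matrix(c("155/155", "155/158"), nrow = 1))
  f <- allele_frequencies(tab, "L01")
  expect_equal(unname(f[c("155", "158")]), c(0.75, 0.25))
  expect_equal(sum(f), 1, tolerance = 1e-12)

  mono <- gt_from_strings(matrix(c("155", "155", "155"), nrow = 1))
  expect_equal(unname(allele_frequencies(mono, "L01")), 1)

  allmiss <- gt_from_strings(matrix(c(".", "."), nrow = 1))
  expect_error(allele_frequencies(allmiss, "L01"), "no typed")
})

test_that("He, Ho and PIC match hand-computed values", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(c(1)), 0)
  expect_equal(expected_heterozygosity(c(0.75, 0.25)), 0.375)
  expect_error(expected_heterozygosity(c(0.5, 0.4)), "sum to 1")

  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)

  tab <- gt_from_strings(matrix(c("155/155", "155/158"), nrow = 1))
  expect_equal(observed_heterozygosity(tab, "L01"), 0.5)
  hom <- gt_from_strings(matrix(c("155/155", "158/158"), nrow = 1))
  expect_equal(observed_heterozygosity(hom, "L01"), 0)

  # small-sample corrected variant
  expect_equal(expected_heterozygosity(c(0.5, 0.5), corrected = TRUE, n = 10),
               0.5 * 20 / 19)
})

test_that("PIC agrees with the explicit pair-sum oracle and never exceeds He", {
  set.seed(50)
  for (r in 1:200) {
    k <- sample(2:8, 1)
    p <- random_simplex(k)
    expect_equal(pic(p), oracle_pic(p), tolerance = 1e-12)
    expect_lte(pic(p), expected_heterozygosity(p))
  }
  # He is maximal (= (n-1)/n) at uniform frequencies
  for (k in 2:10) {
    expect_equal(expected_heterozygosity(rep(1 / k, k)), (k - 1) / k)
  }
})

test_that("null-allele estimates are near zero under Hardy-Weinberg and negative
           under heterozygote excess", {
  gt <- make_genotype_table(n_loci = 1, n_accessions = 4000, n_alleles = 5,
                            f_null = 0, seed = 51)
  expect_lt(abs(null_allele_frequency(gt$table, "locus001")), 0.03)

  allhet <- gt_from_strings(matrix(rep("100/103", 50), nrow = 1))
  expect_lt(null_allele_frequency(allhet, "L01"), 0)

  mono <- gt_from_strings(matrix(rep("100/100", 10), nrow = 1))
  expect_true(is.na(null_allele_frequency(mono, "L01")))
})

test_that("a planted null allele is recovered from apparent homozygote excess", {
  gt <- make_genotype_table(n_loci = 1, n_accessions = 4000, n_alleles = 5,
                            f_null = 0.2, seed = 52)
  est <- null_allele_frequency(gt$table, "locus001")
  expect_lt(abs(est - 0.2), 0.05)
})

test_that("private alleles are exactly those carried by a single accession", {
  tab <- gt_from_strings(rbind(c("155/158", "155/155", "155/161"),
                               c("200/203", "200/203", ".")))
  pa <- private_alleles(tab)
  expect_setequal(pa$allele[pa$locus == "L01"], c(158, 161))
  expect_equal(nrow(pa[pa$locus == "L02", ]), 0L)
  expect_equal(pa$accession[pa$allele == 161], "A03")
})

test_that("diversity statistics and their panel summary are self-consistent", {
  gt <- make_genotype_table(n_loci = 12, n_accessions = 30, seed = 53)
  st <- diversity_stats(gt$table, f_null = FALSE)
  expect_equal(nrow(st), 12L)
  expect_true(all(st$PIC <= st$He + 1e-12))
  expect_true(all(st$He >= 0 & st$He <= 1 & st$Ho >= 0 & st$Ho <= 1))
  expect_true(all(st$He <= 1 - 1 / st$n_alleles + 1e-12))
  s <- summarize_diversity(st)
  expect_equal(s$total_alleles, sum(st$n_alleles))
  expect_equal(s$per_stat$mean[s$per_stat$statistic == "n_alleles"],
               mean(st$n_alleles))
  one <- summarize_diversity(st[1, ])
  expect_equal(one$per_stat$mean, one$per_stat$min)
  expect_equal(one$per_stat$mean, one$per_stat$max)
})

test_that("observed statistics recover the planted panel parameters", {
  gt <- make_genotype_table(n_loci = 3, n_accessions = 5000, n_alleles = 4,
                            f_null = 0, concentration = 3, seed = 54)
  for (l in names(gt$truth)) {
    planted <- gt$truth[[l]]$freqs
    f <- allele_frequencies(gt$table, l)
    expect_equal(unname(f[names(planted)]), unname(planted), tolerance = 0.03)
    expect_equal(expected_heterozygosity(f),
                 expected_heterozygosity(planted), tolerance = 0.01)
  }
})

test_that("genotype tables round-trip through the two-column TSV format", {
  gt <- make_genotype_table(n_loci = 6, n_accessions = 8, f_null = 0.2, seed = 55)
  path <- tempfile(fileext = ".tsv")
  write_genotype_table(gt$table, path)
  back <- read_genotype_table(path)
  expect_equal(back, gt$table)
  first <- readLines(path, n = 1)
  expect_match(first, "^locus\tacc001\\.1\tacc001\\.2")
})
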