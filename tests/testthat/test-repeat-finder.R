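test_that("basic repeat detection honours minimum unit counts", {
  loci <- find_perfect_repeats("ATGATGATGATGATG")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motif, "ATG")
  expect_equal(loci$n_units, 5L)
  expect_equal(c(loci$start, loci$end), c(1L, 15L))

  expect_equal(nrow(find_perfect_repeats("ATGATGATGATG")), 0L)  # 4 units < 5
  expect_equal(nrow(find_perfect_repeats("")), 0L)
  expect_error(find_perfect_repeats("ATGX"), "invalid")
})

test_that("partial trailing units are not counted and runs anchor leftmost", {
  # A + (ATG)x5 + A: repeat reported from the first full unit only
  loci <- find_perfect_repeats(paste0("A", strrep("ATG", 5), "A"))
  expect_equal(nrow(loci), 1L)
  expect_equal(c(loci$start, loci$end, loci$n_units), c(2L, 16L, 5L))
})

test_that("a run is reported only under its shortest period", {
  # A homopolymer is mono, not (AA)n or (AAA)n
  loci <- find_perfect_repeats(strrep("A", 12))
  expect_equal(nrow(loci), 1L)
  expect_equal(nchar(loci$motif), 1L)
  expect_equal(loci$n_units, 12L)
  # (AT)n is di, not tetra (ATAT)
  loci <- find_perfect_repeats(strrep("AT", 8))
  expect_equal(loci$motif, "AT")
  expect_equal(loci$n_units, 8L)
})

test_that("N terminates repeat runs and never joins one", {
  s <- paste0(strrep("ATG", 5), "N", strrep("ATG", 5))
  loci <- find_perfect_repeats(s)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$n_units, c(5L, 5L))
  expect_equal(nrow(find_perfect_repeats(strrep("N", 50))), 0L)
})

test_that("motif canonicalization pools rotations and reverse complements", {
  expect_equal(canonical_motif("CTT"), "AAG")
  expect_equal(canonical_motif("AAG"), "AAG")   # idempotent on canonical form
  expect_equal(canonical_motif("TAG"), "ACT")   # class {TAG,AGT,GTA,CTA,TAC,ACT}
  expect_equal(canonical_motif("ATG"), "ATC")   # revcomp(ATG) rotates to ATC
  expect_error(canonical_motif("AXG"), "invalid")

  set.seed(7)
  for (len in 1:8) {
    for (r in 1:20) {
      m <- random_dna(len)
      cm <- canonical_motif(m)
      expect_equal(canonical_motif(cm), cm)
      expect_equal(canonical_motif(revcomp(m)), cm)
      rot <- sample(len, 1)
      rotated <- paste0(substr(m, rot, len), substr(m, 1, rot - 1))
      expect_equal(canonical_motif(rotated), cm)
    }
  }
})

test_that("A/T-only motifs are recognised", {
  expect_true(is_at_only("AAT"))
  expect_true(is_at_only("ATA"))
  expect_true(is_at_only("T"))
  expect_false(is_at_only("AAG"))
  expect_error(is_at_only(""), "empty")
})

test_that("reported loci agree exactly with the block-chain oracle", {
  set.seed(42)
  cfg <- ssr_search_config()
  for (rep in 1:8) {
    # AT-rich alphabet makes accidental repeats likely
    s <- random_dna(2000, alphabet = c("A", "C", "G", "T", "A", "T"))
    got <- find_perfect_repeats(s, cfg)
    want <- oracle_find_repeats(s, cfg)
    expect_equal(got[, c("start", "end", "motif", "n_units")], want,
                 ignore_attr = TRUE)
  }
  # seeded dense repeat soup
  s <- paste0(random_dna(100), strrep("AAG", 6), random_dna(17),
              strrep("A", 12), strrep("AT", 7), random_dna(50),
              strrep("ACGT", 5), random_dna(100))
  expect_equal(find_perfect_repeats(s)[, c("start", "end", "motif", "n_units")],
               oracle_find_repeats(s), ignore_attr = TRUE)
})

test_that("no two reported loci overlap with the same canonical motif and period", {
  set.seed(11)
  # seed several same-family repeats among random background
  s <- paste0(random_dna(400), strrep("AAG", 6), random_dna(30),
              strrep("GAA", 7), random_dna(200), strrep("CTT", 8),
              random_dna(50), strrep("A", 11), random_dna(120),
              strrep("A", 14), random_dna(400))
  loci <- find_perfect_repeats(s)
  expect_gte(nrow(loci), 5)
  if (nrow(loci) > 1) {
    key <- paste(loci$canonical_motif, nchar(loci$motif))
    for (k in unique(key)) {
      sub <- loci[key == k, , drop = FALSE]
      if (nrow(sub) < 2) next
      sub <- sub[order(sub$start), ]
      expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
  }
})

test_that("planted repeats are recovered with exact coordinates", {
  genome <- make_genome(n_loci = 8, seed = 101)
  found <- find_repeats_in_genome(genome$sequences)
  expect_equal(found[, c("contig", "start", "end", "motif", "n_units")],
               genome$truth[, c("contig", "start", "end", "motif", "n_units")],
               ignore_attr = TRUE)
})

test_that("repeat summaries count families and lengths consistently", {
  empty <- summarize_repeats(find_perfect_repeats(""))
  expect_equal(nrow(empty$by_length), 0L)

  s <- paste0(strrep("A", 10), "C", strrep("G", 10), "C", strrep("T", 10),
              "C", strrep("ATG", 5), "C")
  sm <- summarize_repeats(find_perfect_repeats(s))
  expect_equal(sm$by_length$count[sm$by_length$motif_length == 1], 3L)
  expect_equal(sm$by_length$pct[sm$by_length$motif_length == 1], 75)
  expect_equal(sm$by_length$pct[sm$by_length$motif_length == 3], 25)
  expect_equal(sum(sm$by_length$pct), 100)
  expect_equal(sum(sm$by_family$pct), 100)
  expect_equal(sum(sm$by_family$count), sum(sm$by_length$count))
})
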