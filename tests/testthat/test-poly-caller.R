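test_that("spanning reads yield the read's unit count on either strand", {
  set.seed(10)
  fr <- toy_fragment(random_dna(60), "ATG", 5, random_dna(60))
  read7 <- spanning_read(fr, 7)
  call <- count_units_in_read(read7, fr)
  expect_equal(call$units_observed, 7L)
  expect_false(call$non_integral)
  expect_equal(count_units_in_read(revcomp(read7), fr)$units_observed, 7L)
  expect_equal(count_units_in_read(revcomp(read7), fr)$strand, "-")

  # read ending inside the repeat: right anchor absent -> no call
  partial <- substr(read7, 1, 25 + 3 * 3)
  expect_null(count_units_in_read(partial, fr))

  # one mismatch in an anchor is tolerated, two are not
  mm <- read7
  substr(mm, 15, 15) <- if (substr(mm, 15, 15) == "A") "C" else "A"
  expect_equal(count_units_in_read(mm, fr)$units_observed, 7L)
  expect_equal(count_units_in_read(mm, fr)$flank_mismatches, 1L)
})

test_that("non-integral anchor gaps are flagged, not counted as units", {
  set.seed(11)
  fr <- toy_fragment(random_dna(60), "ATG", 6, random_dna(60))
  # haplotype with one base deleted inside the repeat -> gap not divisible by 3
  left <- substr(fr$sequence, fr$repeat_start - 25, fr$repeat_start - 1)
  right <- substr(fr$sequence, fr$repeat_end + 1, fr$repeat_end + 25)
  read <- paste0(left, substr(strrep("ATG", 6), 1, 17), right)
  call <- count_units_in_read(read, fr)
  expect_true(call$non_integral)
  expect_true(is.na(call$units_observed))
  expect_equal(call$gap_bp, 17L)
})

test_that("locus classification follows the variant-fraction thresholds", {
  mkcalls <- function(units) data.frame(
    locus_id = "L", read_id = sprintf("r%03d", seq_along(units)), strand = "+",
    units_observed = units, non_integral = FALSE, gap_bp = units * 3L,
    left_anchor_pos = 1L, right_anchor_pos = 50L, flank_mismatches = 0L,
    stringsAsFactors = FALSE)

  expect_equal(classify_locus(mkcalls(rep(5L, 100)), 5, 100)$status,
               "not_polymorphic")
  expect_equal(classify_locus(mkcalls(c(rep(5L, 99), 7L)), 5, 100)$status,
               "slightly_polymorphic")  # 1% < 2%
  expect_equal(classify_locus(mkcalls(c(rep(5L, 90), rep(7L, 10))), 5, 100)$status,
               "clearly_polymorphic")   # 10% >= 2%
  expect_equal(classify_locus(NULL, 5, 0)$status, "no_coverage")
  expect_equal(classify_locus(mkcalls(rep(5L, 3)), 5, 50)$status,
               "poor_alignment")        # 3 spanning < 8 despite coverage
  expect_equal(classify_locus(mkcalls(rep(5L, 100)), 5, 100,
                              mapq0_fraction = 0.9)$status, "poor_alignment")

  # exactly at the threshold counts as clearly polymorphic (< 2% is "slight")
  expect_equal(classify_locus(mkcalls(c(rep(5L, 98), 7L, 7L)), 5, 100)$status,
               "clearly_polymorphic")

  # histogram accounting
  cl <- classify_locus(mkcalls(c(rep(5L, 90), rep(7L, 10))), 5, 100)
  expect_equal(sum(cl$unit_histogram), cl$n_spanning)
  expect_equal(unname(cl$unit_histogram[c("5", "7")]), c(90L, 10L))
})

test_that("single non-integral reads are noise; two agreeing reads are evidence", {
  base <- data.frame(
    locus_id = "L", read_id = "r", strand = "+", units_observed = 5L,
    non_integral = FALSE, gap_bp = 15L, left_anchor_pos = 1L,
    right_anchor_pos = 50L, flank_mismatches = 0L, stringsAsFactors = FALSE)
  calls <- base[rep(1, 50), ]
  ni <- base; ni$non_integral <- TRUE; ni$units_observed <- NA_integer_; ni$gap_bp <- 16L
  one <- rbind(calls, ni)
  expect_equal(classify_locus(one, 5, 60)$n_variant, 0L)
  two <- rbind(calls, ni, ni)
  expect_equal(classify_locus(two, 5, 60)$n_variant, 2L)
})

test_that("classification is symmetric under reverse complement of all reads", {
  g <- make_genome(n_loci = 4, seed = 21)
  fr <- extract_fragments(g$sequences, g$truth)
  rd <- make_reads(g, variant_loci = g$truth$locus_id[1:2], coverage = 8,
                   seed = 22)
  fwd <- classify_loci(rd$reads_by_locus, fr)
  rc <- lapply(rd$reads_by_locus, revcomp)
  rev <- classify_loci(rc, fr)
  expect_equal(fwd$status, rev$status)
  expect_equal(fwd$n_spanning, rev$n_spanning)
  expect_equal(fwd$n_variant, rev$n_variant)
})

test_that("adding a variant spanning read never demotes a clearly polymorphic locus", {
  set.seed(23)
  fr <- toy_fragment(random_dna(60), "ATG", 5, random_dna(60))
  reads <- c(replicate(40, spanning_read(fr, 5)), replicate(5, spanning_read(fr, 7)))
  st0 <- classify_loci(list(toy = reads), list(toy = fr))$status
  expect_equal(st0, "clearly_polymorphic")
  for (extra in 1:3) {
    reads <- c(reads, spanning_read(fr, 8))
    expect_equal(classify_loci(list(toy = reads), list(toy = fr))$status,
                 "clearly_polymorphic")
  }
})

test_that("SAM pipeline matches in-memory classification and handles edge cases", {
  g <- make_genome(n_loci = 3, seed = 31)
  fr <- extract_fragments(g$sequences, g$truth)
  rd <- make_reads(g, variant_loci = g$truth$locus_id[1], coverage = 8, seed = 32)
  mem <- classify_loci(rd$reads_by_locus, fr)
  dir <- tempfile(); paths <- write_read_fixture(rd$reads_by_locus, fr, dir)
  sam <- call_pipeline(paths$sam, fr)
  expect_equal(mem$status, sam$status)
  expect_equal(mem$n_spanning, sam$n_spanning)

  # empty SAM (header only): every locus no_coverage
  empty_sam <- file.path(dir, "empty.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(fr),
                       vapply(fr, function(f) nchar(f$sequence), integer(1)))),
             empty_sam)
  cl <- call_pipeline(empty_sam, fr)
  expect_true(all(cl$status == "no_coverage"))

  # reference-name mismatch is an error
  expect_error(call_pipeline(paths$sam, fr[1:2]), "not present")
})
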