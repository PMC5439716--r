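# Deterministic simulator for validation inputs: genomes with planted
# perfect repeats, cultivar read sets with planted repeat-unit variants,
# ideal SAM alignments, and genotype tables drawn under Hardy-Weinberg with
# optional null alleles. Every generator is a pure function of its seed and
# ships a ground-truth manifest; end-to-end tests assert against manifests,
# never against re-derived values. R's default Mersenne-Twister stream is
# used throughout (one stream per fixture, keyed by the seed).

.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a genome with planted perfect repeats
#'
#' One contig per planted locus: random background, the repeat, random
#' background. Each contig is rejection-sampled until the repeat detector
#' run with `config` finds exactly the planted repeat at exactly the
#' planted coordinates, so the background is guaranteed free of accidental
#' above-threshold repeats and the planted repeat is not extended by
#' chance.
#'
#' @param n_loci Number of planted repeat loci (one per contig).
#' @param motifs Character vector of motifs to plant (recycled/sampled).
#' @param unit_range Length-2 integer range of planted repeat-unit counts.
#' @param flank_len Background length on each side of the repeat (default
#'   300 bp).
#' @param gc Background GC fraction.
#' @param config `ssr_search_config` used for the accidental-repeat screen.
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @return List with `sequences` (named character vector of contigs) and
#'   `truth` (data.frame `locus_id`, `contig`, `start`, `end`, `motif`,
#'   `n_units`, 1-based inclusive), plus the generator settings in
#'   `manifest`.
#' @export
make_genome <- function(n_loci = 10, motifs = c("ATG", "AAG", "ATC", "ACC"),
                        unit_range = c(6L, 12L), flank_len = 300L, gc = 0.5,
                        config = ssr_search_config(), seed = 1L) {
  if (n_loci < 0) stop("n_loci must be nonnegative")
  set.seed(seed)
  seqs <- character(n_loci)
  truth <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    motif <- motifs[((i - 1L) %% length(motifs)) + 1L]
    units <- sample(seq(unit_range[1], unit_range[2]), 1)
    contig_id <- sprintf("contig%03d", i)
    ok <- FALSE
    for (try in 1:100) {
      left <- .random_dna(flank_len, gc)
      right <- .random_dna(flank_len, gc)
      contig <- paste0(left, strrep(motif, units), right)
      found <- find_perfect_repeats(contig, config, contig_id = contig_id)
      if (nrow(found) == 1 && found$start == flank_len + 1L &&
          found$end == flank_len + units * nchar(motif) &&
          found$motif == motif) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place locus ", i, " without accidental repeats")
    seqs[i] <- contig
    names(seqs)[i] <- contig_id
    truth[[i]] <- data.frame(
      locus_id = sprintf("%s_ssr%04d", contig_id, 1L), contig = contig_id,
      start = flank_len + 1L, end = flank_len + units * nchar(motif),
      motif = motif, n_units = units, stringsAsFactors = FALSE)
  }
  truth <- if (n_loci > 0) do.call(rbind, truth) else
    data.frame(locus_id = character(), contig = character(), start = integer(),
               end = integer(), motif = character(), n_units = integer(),
               stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth,
       manifest = list(generator = "make_genome", seed = seed,
                       n_loci = n_loci, unit_range = unit_range,
                       flank_len = flank_len, gc = gc,
                       rng = "Mersenne-Twister"))
}

.add_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    if (length(hit)) {
      for (h in hit) ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.sample_reads <- function(hap, n_reads, read_length, prefix) {
  L <- nchar(hap)
  if (L < read_length || n_reads <= 0) return(character())
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  reads <- substring(hap, starts, starts + read_length - 1L)
  names(reads) <- sprintf("%s_r%05d_p%d", prefix, seq_len(n_reads), starts)
  attr(reads, "starts") <- starts
  reads
}

#' Simulate pooled cultivar reads over planted repeat loci
#'
#' Each cultivar carries, per locus, either the reference haplotype or a
#' haplotype whose only difference is the planted repeat-unit change.
#' Single-end reads start uniformly along the haplotype; optional
#' substitution errors are applied at `error_rate` per base. Reads are
#' pooled across cultivars without cultivar attribution, mirroring the
#' pooled-alignment design the classifier expects.
#'
#' @param genome Result of [make_genome()].
#' @param n_cultivars Number of resequenced cultivars (default 7).
#' @param variant_loci Character vector of truth locus_ids that are
#'   polymorphic among the cultivars.
#' @param n_variant_cultivars Cultivars (out of `n_cultivars`) carrying the
#'   variant haplotype at each variant locus (default 3).
#' @param delta_units Repeat-unit change in variant haplotypes (default
#'   +2).
#' @param coverage Per-cultivar sequencing depth (default 20).
#' @param read_length Read length in bp (default 100).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @return List with `reads_by_locus` (named list of pooled read vectors,
#'   keyed by truth locus_id), `truth` (data.frame locus_id, is_variant,
#'   delta_units, n_variant_cultivars, expected_variant_fraction) and
#'   `manifest`.
#' @export
make_reads <- function(genome, n_cultivars = 7L, variant_loci = character(),
                       n_variant_cultivars = 3L, delta_units = 2L,
                       coverage = 20, read_length = 100L, error_rate = 0,
                       seed = 1L) {
  set.seed(seed)
  truth <- genome$truth
  if (!all(variant_loci %in% truth$locus_id)) {
    stop("variant_loci must be planted locus_ids")
  }
  reads_by_locus <- vector("list", nrow(truth))
  names(reads_by_locus) <- truth$locus_id
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    ref <- genome$sequences[[row$contig]]
    is_var <- row$locus_id %in% variant_loci
    var_hap <- NULL
    if (is_var) {
      var_hap <- paste0(substr(ref, 1L, row$start - 1L),
                        strrep(row$motif, row$n_units + delta_units),
                        substr(ref, row$end + 1L, nchar(ref)))
    }
    pooled <- character()
    for (cv in seq_len(n_cultivars)) {
      hap <- if (is_var && cv <= n_variant_cultivars) var_hap else ref
      n_reads <- round(coverage * nchar(hap) / read_length)
      rd <- .sample_reads(hap, n_reads, read_length,
                          sprintf("%s_c%02d", row$locus_id, cv))
      pooled <- c(pooled, rd)
    }
    pooled[] <- .add_substitution_errors(unname(pooled), error_rate)
    reads_by_locus[[i]] <- pooled
  }
  rtruth <- data.frame(
    locus_id = truth$locus_id,
    is_variant = truth$locus_id %in% variant_loci,
    delta_units = ifelse(truth$locus_id %in% variant_loci, delta_units, 0L),
    n_variant_cultivars = ifelse(truth$locus_id %in% variant_loci,
                                 n_variant_cultivars, 0L),
    expected_variant_fraction = ifelse(truth$locus_id %in% variant_loci,
                                       n_variant_cultivars / n_cultivars, 0),
    stringsAsFactors = FALSE)
  list(reads_by_locus = reads_by_locus, truth = rtruth,
       manifest = list(generator = "make_reads", seed = seed,
                       n_cultivars = n_cultivars, coverage = coverage,
                       read_length = read_length, error_rate = error_rate,
                       delta_units = delta_units,
                       rng = "Mersenne-Twister"))
}

#' Simulate reads for one locus at an exact variant-read fraction
#'
#' Constructs a read set in which exactly `round(n_reads *
#' variant_fraction)` reads come from the variant haplotype, for testing
#' classification thresholds at controlled fractions.
#'
#' @param contig_seq Reference contig sequence.
#' @param truth_row One row of a genome truth data.frame.
#' @param n_reads Total reads to draw.
#' @param variant_fraction Fraction of reads from the variant haplotype.
#' @param delta_units Repeat-unit change of the variant haplotype.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Named character vector of reads.
#' @export
simulate_locus_reads <- function(contig_seq, truth_row, n_reads,
                                 variant_fraction = 0, delta_units = 2L,
                                 read_length = 100L, error_rate = 0,
                                 seed = 1L) {
  set.seed(seed)
  n_var <- round(n_reads * variant_fraction)
  var_hap <- paste0(substr(contig_seq, 1L, truth_row$start - 1L),
                    strrep(truth_row$motif, truth_row$n_units + delta_units),
                    substr(contig_seq, truth_row$end + 1L, nchar(contig_seq)))
  reads <- c(.sample_reads(contig_seq, n_reads - n_var, read_length, "ref"),
             .sample_reads(var_hap, n_var, read_length, "var"))
  reads[] <- .add_substitution_errors(unname(reads), error_rate)
  reads
}

#' Write simulated reads as FASTQ and an ideal SAM alignment
#'
#' Emits one pooled FASTQ (constant quality) and a SAM file whose
#' references are the fragment locus_ids, placing every read on its source
#' fragment at mapping quality 60 on the forward strand (the simulator
#' knows the true origin; positions are nominal since the classifier uses
#' only reference assignment and sequence).
#'
#' @param reads_by_locus Named list of read vectors (keys must match
#'   fragment locus_ids).
#' @param fragments Named list of `ssr_fragment` objects (alignment
#'   references).
#' @param dir Output directory (created if needed).
#' @return Paths of the written files (`fastq`, `sam`).
#' @export
write_read_fixture <- function(reads_by_locus, fragments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fastq <- file.path(dir, "pooled.fastq")
  sam <- file.path(dir, "alignments.sam")
  fq <- character()
  recs <- character()
  for (id in names(fragments)) {
    fr <- fragments[[id]]
    reads <- reads_by_locus[[id]]
    if (is.null(reads) || length(reads) == 0) next
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("%s_r%05d", id, seq_along(reads))
    qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    fq <- c(fq, as.vector(rbind(paste0("@", ids), unname(reads), "+", qual)))
    recs <- c(recs, paste(ids, 0L, id, 1L, 60L,
                          paste0(nchar(reads), "M"), "*", 0L, 0L,
                          unname(reads), qual, sep = "\t"))
  }
  writeLines(fq, fastq)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              vapply(names(fragments), function(id) {
                sprintf("@SQ\tSN:%s\tLN:%d", id,
                        nchar(fragments[[id]]$sequence))
              }, character(1)))
  writeLines(c(header, recs), sam)
  list(fastq = fastq, sam = sam)
}

#' Simulate a genotype table under Hardy-Weinberg with optional null allele
#'
#' Per locus, diploid genotypes are drawn from the given visible-allele
#' frequencies plus a null allele at frequency `f_null`. Null homozygotes
#' become missing calls; null heterozygotes appear as homozygotes for
#' their visible allele. Allele sizes are `base_size + 3 * k` (tri-
#' nucleotide ladder).
#'
#' @param n_loci Number of loci (default 132).
#' @param n_accessions Number of accessions (default 50).
#' @param n_alleles Integer vector (length 1 or n_loci) of visible allele
#'   counts per locus; default draws 2-13 with mean near 4.7.
#' @param f_null Null-allele frequency (length 1 or n_loci; default 0).
#' @param concentration Dirichlet concentration for the visible allele
#'   frequencies (default 1 = uniform simplex).
#' @param base_size Smallest allele size in bp (default 150).
#' @param seed Integer seed.
#' @return List with `table` (a `genotype_table`), `truth` (list per locus:
#'   `freqs` named visible-allele frequencies, `f_null`) and `manifest`.
#' @export
make_genotype_table <- function(n_loci = 132L, n_accessions = 50L,
                                n_alleles = NULL, f_null = 0,
                                concentration = 1, base_size = 150L,
                                seed = 1L) {
  set.seed(seed)
  if (is.null(n_alleles)) {
    # 2..13 skewed low: mean ~ 4.7, matching a realistic SSR panel
    n_alleles <- 2L + stats::rbinom(n_loci, size = 11L, prob = 0.245)
  }
  n_alleles <- rep_len(as.integer(n_alleles), n_loci)
  if (any(n_alleles < 1)) stop("invalid allele counts")
  f_null <- rep_len(f_null, n_loci)
  if (any(f_null < 0 | f_null >= 1)) stop("f_null must be in [0, 1)")
  a1 <- matrix(NA_integer_, n_loci, n_accessions)
  a2 <- matrix(NA_integer_, n_loci, n_accessions)
  truth <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    k <- n_alleles[l]
    g <- stats::rgamma(k, shape = concentration)
    p_vis <- g / sum(g)
    sizes <- base_size + 3L * seq_len(k)
    p_all <- c(p_vis * (1 - f_null[l]), f_null[l])  # last = null
    draw1 <- sample.int(k + 1L, n_accessions, replace = TRUE, prob = p_all)
    draw2 <- sample.int(k + 1L, n_accessions, replace = TRUE, prob = p_all)
    null1 <- draw1 == k + 1L; null2 <- draw2 == k + 1L
    for (j in seq_len(n_accessions)) {
      if (null1[j] && null2[j]) next  # null homozygote: missing
      if (null1[j]) { a1[l, j] <- a2[l, j] <- sizes[draw2[j]]; next }
      if (null2[j]) { a1[l, j] <- a2[l, j] <- sizes[draw1[j]]; next }
      pair <- sort(c(sizes[draw1[j]], sizes[draw2[j]]))
      a1[l, j] <- pair[1]; a2[l, j] <- pair[2]
    }
    truth[[l]] <- list(freqs = stats::setNames(p_vis, sizes),
                       f_null = f_null[l])
  }
  loci <- sprintf("locus%03d", seq_len(n_loci))
  accs <- sprintf("acc%03d", seq_len(n_accessions))
  names(truth) <- loci
  list(table = genotype_table(a1, a2, loci = loci, accessions = accs),
       truth = truth,
       manifest = list(generator = "make_genotype_table", seed = seed,
                       n_loci = n_loci, n_accessions = n_accessions,
                       rng = "Mersenne-Twister"))
}
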