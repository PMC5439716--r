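# Marker characterization statistics: allele frequencies, expected and
# observed heterozygosity, polymorphism information content, null-allele
# frequency, private alleles.

#' Construct a genotype table
#'
#' A rectangular loci x accessions table of co-dominant SSR calls. Each cell
#' is an unordered pair of integer allele sizes (bp); a homozygote carries
#' the same size twice; missing calls are NA in both matrices. Accessions
#' with more than two amplicons at a locus cannot be represented here and
#' are excluded from characterization (kept in a separate multi-amplicon
#' table upstream).
#'
#' @param allele1,allele2 Integer matrices (loci x accessions) of allele
#'   sizes; NA = missing. `allele2` defaults to `allele1` (all homozygous).
#' @param loci,accessions Character vectors of row/column names.
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(allele1, allele2 = allele1,
                           loci = rownames(allele1),
                           accessions = colnames(allele1)) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  stopifnot(all(dim(allele1) == dim(allele2)))
  if (is.null(loci)) loci <- sprintf("locus%03d", seq_len(nrow(allele1)))
  if (is.null(accessions)) accessions <- sprintf("acc%03d", seq_len(ncol(allele1)))
  if (any(xor(is.na(allele1), is.na(allele2)))) {
    stop("half-missing calls: allele1 and allele2 must be NA together")
  }
  if (any(allele1 <= 0, na.rm = TRUE) || any(allele2 <= 0, na.rm = TRUE)) {
    stop("allele sizes must be positive")
  }
  # store pairs in sorted order so the pair is unordered
  swap <- !is.na(allele1) & allele1 > allele2
  tmp <- allele1[swap]; allele1[swap] <- allele2[swap]; allele2[swap] <- tmp
  dimnames(allele1) <- dimnames(allele2) <- list(loci, accessions)
  structure(list(loci = loci, accessions = accessions,
                 allele1 = allele1, allele2 = allele2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$loci), "loci x", length(x$accessions),
      "accessions;", sum(is.na(x$allele1)), "missing calls\n")
  invisible(x)
}

.locus_calls <- function(table, locus) {
  i <- match(locus, table$loci)
  if (is.na(i)) stop("locus ", locus, " not in table")
  a1 <- table$allele1[i, ]; a2 <- table$allele2[i, ]
  typed <- !is.na(a1)
  list(a1 = a1[typed], a2 = a2[typed], n_typed = sum(typed),
       accessions = table$accessions[typed])
}

#' Allele frequencies at a locus
#'
#' Each homozygote contributes two copies of its allele and each
#' heterozygote one copy of each; missing calls are excluded.
#'
#' @param table `genotype_table`.
#' @param locus Locus identifier.
#' @return Named numeric vector of frequencies (names = allele sizes),
#'   summing to 1, sorted by allele size.
#' @export
allele_frequencies <- function(table, locus) {
  calls <- .locus_calls(table, locus)
  if (calls$n_typed == 0) stop("no typed accessions at locus ", locus)
  counts <- table(c(calls$a1, calls$a2))
  freqs <- as.numeric(counts) / sum(counts)
  names(freqs) <- names(counts)
  freqs[order(as.integer(names(freqs)))]
}

#' Expected heterozygosity (gene diversity)
#'
#' He = 1 - sum(p_i^2). The plain (biased) estimator is the default, the
#' formula used by the marker-characterization convention this package
#' follows; `corrected = TRUE` applies the small-sample factor
#' 2n/(2n - 1) used by some software.
#'
#' @param freqs Named numeric vector of allele frequencies (sum to 1).
#' @param corrected Apply the 2n/(2n-1) correction (requires `n`).
#' @param n Number of typed diploid individuals (only with `corrected`).
#' @return He in [0, 1].
#' @export
expected_heterozygosity <- function(freqs, corrected = FALSE, n = NULL) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  he <- 1 - sum(freqs^2)
  if (corrected) {
    if (is.null(n)) stop("'n' required for the small-sample correction")
    he <- he * 2 * n / (2 * n - 1)
  }
  he
}

#' Observed heterozygosity at a locus
#'
#' Number of heterozygous genotypes divided by the number of typed
#' genotypes.
#'
#' @inheritParams allele_frequencies
#' @return Ho in [0, 1].
#' @export
observed_heterozygosity <- function(table, locus) {
  calls <- .locus_calls(table, locus)
  if (calls$n_typed == 0) stop("no typed accessions at locus ", locus)
  mean(calls$a1 != calls$a2)
}

#' Polymorphism information content (Botstein)
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2, computed via the
#' power-sum identity sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4.
#' Always <= He.
#'
#' @param freqs Named numeric vector of allele frequencies (sum to 1).
#' @return PIC in [0, 1].
#' @export
pic <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  s2 <- sum(freqs^2); s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

# Negative log-likelihood of apparent genotype counts under the null-allele
# model, conditional on amplification. par = c(p0, z_2..z_k); visible
# frequencies are softmax(c(0, z)) scaled to (1 - p0).
.null_nll <- function(par, hom_counts, het_counts, het_pairs, k) {
  p0 <- par[1]
  if (p0 <= -0.95 || p0 >= 0.95) return(1e10)
  w <- exp(c(0, par[-1]))
  p <- w / sum(w) * (1 - p0)
  phom <- p^2 + 2 * p * p0
  if (any(phom <= 0) || (1 - p0^2) <= 0) return(1e10)
  ll <- sum(hom_counts * log(phom))
  if (length(het_counts)) {
    ll <- ll + sum(het_counts * log(2 * p[het_pairs[, 1]] * p[het_pairs[, 2]]))
  }
  n <- sum(hom_counts) + sum(het_counts)
  -(ll - n * log(1 - p0^2))
}

#' Null-allele frequency (maximum likelihood)
#'
#' Estimates the frequency of a non-amplifying (null) allele from the
#' excess of apparent homozygotes relative to Hardy-Weinberg expectation.
#' Under the model, a null heterozygote i/0 is observed as an apparent
#' homozygote i/i and a null homozygote fails to amplify, so the likelihood
#' of the apparent genotype counts, conditional on amplification, is
#' P(i/i) = (p_i^2 + 2 p_i p_0) / (1 - p_0^2) and
#' P(i/j) = 2 p_i p_j / (1 - p_0^2). The likelihood is maximized
#' numerically over the null frequency p_0 and the visible allele
#' frequencies, with p_0 unconstrained in sign so that heterozygote excess
#' yields a negative estimate (as null-allele estimates conventionally
#' behave).
#'
#' @inheritParams allele_frequencies
#' @return Estimated null-allele frequency (may be negative), or NA for a
#'   monomorphic locus.
#' @export
null_allele_frequency <- function(table, locus) {
  calls <- .locus_calls(table, locus)
  if (calls$n_typed == 0) stop("no typed accessions at locus ", locus)
  alleles <- sort(unique(c(calls$a1, calls$a2)))
  k <- length(alleles)
  if (k < 2) return(NA_real_)
  i1 <- match(calls$a1, alleles); i2 <- match(calls$a2, alleles)
  hom_counts <- tabulate(i1[i1 == i2], nbins = k)
  het <- i1 != i2
  het_key <- paste(i1[het], i2[het])
  het_tab <- table(het_key)
  het_pairs <- do.call(rbind, lapply(strsplit(names(het_tab), " "), as.integer))
  het_counts <- as.integer(het_tab)
  if (is.null(het_pairs)) het_pairs <- matrix(integer(), ncol = 2)
  # moment-based start (Chakraborty): (He - Ho) / (He + Ho)
  freqs <- allele_frequencies(table, locus)
  he <- expected_heterozygosity(freqs)
  ho <- observed_heterozygosity(table, locus)
  p0_start <- if (he + ho > 0) (he - ho) / (he + ho) else 0
  p0_start <- max(-0.5, min(0.8, p0_start))
  w_start <- pmax(freqs, 1e-6)
  par0 <- c(p0_start, log(w_start[-1] / w_start[1]))
  fit <- stats::optim(par0, .null_nll, hom_counts = hom_counts,
                      het_counts = het_counts, het_pairs = het_pairs, k = k,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  fit2 <- tryCatch(
    stats::optim(fit$par, .null_nll, hom_counts = hom_counts,
                 het_counts = het_counts, het_pairs = het_pairs, k = k,
                 method = "BFGS", control = list(maxit = 500)),
    error = function(e) fit)
  if (fit2$value <= fit$value) fit <- fit2
  unname(fit$par[1])
}

#' Private alleles in a genotype table
#'
#' Alleles carried by exactly one accession (regardless of dosage) across
#' the panel.
#'
#' @param table `genotype_table`.
#' @return data.frame with columns `locus`, `allele`, `accession`.
#' @export
private_alleles <- function(table) {
  rows <- list()
  for (locus in table$loci) {
    calls <- .locus_calls(table, locus)
    if (calls$n_typed == 0) next
    for (allele in sort(unique(c(calls$a1, calls$a2)))) {
      carriers <- calls$accessions[calls$a1 == allele | calls$a2 == allele]
      if (length(carriers) == 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = locus, allele = allele, accession = carriers,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus = character(), allele = integer(),
                      accession = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-locus diversity statistics
#'
#' @param table `genotype_table`.
#' @param f_null Also estimate the null-allele frequency (default TRUE;
#'   numerical optimisation per locus).
#' @return data.frame of class `diversity_stats`: `locus_id`, `n_alleles`,
#'   `He`, `Ho`, `PIC`, `f_null`, `n_typed`.
#' @export
diversity_stats <- function(table, f_null = TRUE) {
  rows <- lapply(table$loci, function(locus) {
    freqs <- allele_frequencies(table, locus)
    calls <- .locus_calls(table, locus)
    data.frame(
      locus_id = locus, n_alleles = length(freqs),
      He = expected_heterozygosity(freqs),
      Ho = observed_heterozygosity(table, locus),
      PIC = pic(freqs),
      f_null = if (f_null) null_allele_frequency(table, locus) else NA_real_,
      n_typed = calls$n_typed, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("diversity_stats", "data.frame")
  res
}

#' Panel-level summary of diversity statistics
#'
#' @param stats `diversity_stats` data.frame.
#' @return List with `total_alleles` and a data.frame `per_stat` of
#'   mean/min/max for n_alleles, He, Ho, PIC and f_null.
#' @export
summarize_diversity <- function(stats) {
  if (nrow(stats) == 0) stop("empty diversity statistics")
  cols <- c("n_alleles", "He", "Ho", "PIC", "f_null")
  per_stat <- do.call(rbind, lapply(cols, function(cn) {
    v <- stats[[cn]][!is.na(stats[[cn]])]
    if (length(v) == 0) v <- NA_real_
    data.frame(statistic = cn, mean = mean(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  list(total_alleles = sum(stats$n_alleles), per_stat = per_stat)
}

#' Write a genotype table as TSV
#'
#' One row per locus; two columns per accession (`<acc>.1`, `<acc>.2`);
#' homozygotes repeat the allele; "." marks missing.
#'
#' @param table `genotype_table`.
#' @param path Output path.
#' @export
write_genotype_table <- function(table, path) {
  fmt <- function(m) { m2 <- matrix(as.character(m), nrow = nrow(m)); m2[is.na(m2)] <- "."; m2 }
  a1 <- fmt(table$allele1); a2 <- fmt(table$allele2)
  out <- matrix("", nrow = length(table$loci), ncol = 2 * length(table$accessions))
  out[, seq(1, ncol(out), 2)] <- a1
  out[, seq(2, ncol(out), 2)] <- a2
  colnames(out) <- as.vector(rbind(paste0(table$accessions, ".1"),
                                   paste0(table$accessions, ".2")))
  df <- data.frame(locus = table$loci, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table from TSV
#'
#' @param path TSV written by [write_genotype_table()] (or transcribed to
#'   the same layout).
#' @return `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  loci <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(body) %% 2 != 0) stop("expected two columns per accession")
  accs <- sub("\\.1$", "", colnames(body)[seq(1, ncol(body), 2)])
  a1 <- body[, seq(1, ncol(body), 2), drop = FALSE]
  a2 <- body[, seq(2, ncol(body), 2), drop = FALSE]
  conv <- function(m) { m[m == "."] <- NA; matrix(as.integer(m), nrow = nrow(m)) }
  genotype_table(conv(a1), conv(a2), loci = loci, accessions = accs)
}
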