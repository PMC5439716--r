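# Detection of maximal perfect tandem repeats (MISA-style search).

#' Search configuration for perfect-repeat detection
#'
#' Minimum numbers of repeat units per motif length follow the MISA criteria
#' used for marker mining: mono 10, di 6, tri 5, tetra/penta/hexa 4.
#' Hepta- and octa-nucleotide minima default to 3 and are configurable.
#'
#' @param min_units Named integer vector mapping motif length ("1".."8") to
#'   the minimum number of repeat units required to report a locus. All
#'   minima must be >= 2.
#' @param motif_lengths Integer vector of motif lengths to search (subset of
#'   1:8).
#' @param exclude_at_only Logical; if `TRUE`, loci whose motif contains only
#'   A and T are dropped (such repeats are hard to score and are removed
#'   before marker development).
#' @return An object of class `ssr_search_config`.
#' @export
ssr_search_config <- function(min_units = c("1" = 10L, "2" = 6L, "3" = 5L,
                                            "4" = 4L, "5" = 4L, "6" = 4L,
                                            "7" = 3L, "8" = 3L),
                              motif_lengths = 1:8,
                              exclude_at_only = FALSE) {
  if (is.null(names(min_units))) names(min_units) <- as.character(seq_along(min_units))
  min_units <- vapply(min_units, as.integer, integer(1))
  if (any(min_units < 2L)) stop("all minimum unit counts must be >= 2")
  motif_lengths <- sort(unique(as.integer(motif_lengths)))
  if (any(motif_lengths < 1L | motif_lengths > 8L)) {
    stop("motif lengths must be between 1 and 8")
  }
  missing_len <- setdiff(as.character(motif_lengths), names(min_units))
  if (length(missing_len) > 0) {
    stop("no minimum unit count configured for motif length(s) ",
         paste(missing_len, collapse = ", "))
  }
  structure(list(min_units = min_units, motif_lengths = motif_lengths,
                 exclude_at_only = isTRUE(exclude_at_only)),
            class = "ssr_search_config")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of plain character DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(DNA_COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.check_motif <- function(motif) {
  if (any(!nzchar(motif))) stop("empty motif")
  bad <- grepl("[^ACGT]", motif)
  if (any(bad)) stop("invalid characters in motif: ", paste(motif[bad], collapse = ", "))
  invisible(motif)
}

.rotations <- function(s) {
  n <- nchar(s)
  if (n == 1) return(s)
  doubled <- paste0(s, s)
  substring(doubled, 1:n, n:(2 * n - 1))
}

#' Canonical form of a repeat motif
#'
#' The canonical motif is the lexicographically smallest string among all
#' cyclic rotations of the motif and of its reverse complement, so that a
#' motif family such as AAG/CTT is reported under a single representative
#' regardless of strand and phase.
#'
#' @param motif Character vector of motifs (1-8 bp, A/C/G/T).
#' @return Character vector of canonical motifs. Idempotent and invariant
#'   under rotation and reverse complement.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  .check_motif(motif)
  vapply(motif, function(m) {
    min(c(.rotations(m), .rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Does a motif contain only A and T?
#'
#' Repeats whose motif contains only A and T are removed from the marker
#' pipeline before fragment extraction.
#'
#' @param motif Character vector of motifs.
#' @return Logical vector.
#' @export
is_at_only <- function(motif) {
  motif <- toupper(motif)
  if (any(!nzchar(motif))) stop("empty motif")
  !grepl("[^AT]", motif)
}

#' Motif family label (canonical motif / its reverse complement)
#' @param motif Character vector of motifs.
#' @return Character vector such as "AAG/CTT".
#' @export
motif_family <- function(motif) {
  canon <- canonical_motif(motif)
  paste0(canon, "/", revcomp(canon))
}

# TRUE iff the motif is not a whole number of copies of a shorter string.
.is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1) return(TRUE)
  for (q in seq_len(p - 1)) {
    if (p %% q == 0 && strrep(substr(motif, 1, q), p %/% q) == motif) return(FALSE)
  }
  TRUE
}

#' Find maximal perfect tandem repeats in a DNA sequence
#'
#' Reports every maximal perfect repeat meeting the configured minimum unit
#' count for its motif length. A run that is reportable under several motif
#' lengths (e.g. an A homopolymer, which is also a perfect (AA)n run) is
#' reported only under its shortest period; partial trailing units are not
#' counted. N never participates in a repeat. Compound or interrupted
#' repeats are not modelled: only perfect repeats are reported.
#'
#' @param sequence A single DNA string over A/C/G/T/N (case-insensitive).
#' @param config An [ssr_search_config()] object.
#' @param contig_id Contig name recorded in the output.
#' @return A data.frame of class `ssr_loci` with columns `locus_id`,
#'   `contig`, `start`, `end` (1-based, inclusive), `motif`,
#'   `canonical_motif`, `family`, `n_units` and `length`, sorted by start.
#' @export
find_perfect_repeats <- function(sequence, config = ssr_search_config(),
                                 contig_id = "contig") {
  stopifnot(inherits(config, "ssr_search_config"))
  if (length(sequence) != 1) stop("'sequence' must be a single string")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("invalid characters in sequence")
  n <- nchar(sequence)
  out <- list()
  if (n > 0) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    usable <- chars != "N"
    for (p in config$motif_lengths) {
      minu <- config$min_units[[as.character(p)]]
      if (n < p * minu) next
      # match vector: position i pairs with i + p
      m <- chars[seq_len(n - p)] == chars[(p + 1):n]
      m <- m & usable[seq_len(n - p)] & usable[(p + 1):n]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= (minu - 1L) * p
      for (k in which(keep)) {
        i <- starts[k]
        units <- (r$lengths[k] + p) %/% p
        if (units < minu) next
        motif <- substr(sequence, i, i + p - 1L)
        if (!.is_primitive(motif)) next
        out[[length(out) + 1L]] <- data.frame(
          contig = contig_id, start = i, end = i + units * p - 1L,
          motif = motif, n_units = units, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(locus_id = character(), contig = character(),
                      start = integer(), end = integer(), motif = character(),
                      canonical_motif = character(), family = character(),
                      n_units = integer(), length = integer(),
                      stringsAsFactors = FALSE)
    class(res) <- c("ssr_loci", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, nchar(res$motif)), , drop = FALSE]
  res$canonical_motif <- canonical_motif(res$motif)
  if (config$exclude_at_only) res <- res[!is_at_only(res$motif), , drop = FALSE]
  res$family <- if (nrow(res)) motif_family(res$motif) else character()
  res$length <- res$end - res$start + 1L
  res$locus_id <- sprintf("%s_ssr%04d", res$contig, seq_len(nrow(res)))
  rownames(res) <- NULL
  res <- res[, c("locus_id", "contig", "start", "end", "motif",
                 "canonical_motif", "family", "n_units", "length")]
  class(res) <- c("ssr_loci", "data.frame")
  res
}

#' Find perfect repeats across a set of contigs
#'
#' @param sequences Named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param config An [ssr_search_config()].
#' @return An `ssr_loci` data.frame over all contigs.
#' @export
find_repeats_in_genome <- function(sequences, config = ssr_search_config()) {
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("contig%03d", seq_along(sequences))
  }
  res <- do.call(rbind, lapply(names(sequences), function(id) {
    find_perfect_repeats(sequences[[id]], config, contig_id = id)
  }))
  if (is.null(res)) res <- find_perfect_repeats("", config)
  class(res) <- c("ssr_loci", "data.frame")
  res
}

#' Summarize repeats by motif length and canonical family
#'
#' @param loci An `ssr_loci` data.frame.
#' @return A list with `by_length` (motif length, count, pct) and
#'   `by_family` (family, count, pct), percentages of the total locus count.
#' @export
summarize_repeats <- function(loci) {
  if (nrow(loci) == 0) {
    return(list(
      by_length = data.frame(motif_length = integer(), count = integer(),
                             pct = numeric()),
      by_family = data.frame(family = character(), count = integer(),
                             pct = numeric(), stringsAsFactors = FALSE)))
  }
  len <- nchar(loci$motif)
  tl <- table(len)
  by_length <- data.frame(motif_length = as.integer(names(tl)),
                          count = as.integer(tl),
                          pct = 100 * as.integer(tl) / nrow(loci))
  tf <- sort(table(loci$family), decreasing = TRUE)
  by_family <- data.frame(family = names(tf), count = as.integer(tf),
                          pct = 100 * as.integer(tf) / nrow(loci),
                          stringsAsFactors = FALSE)
  rownames(by_family) <- NULL
  list(by_length = by_length, by_family = by_family)
}
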