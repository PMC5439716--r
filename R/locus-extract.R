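# Fragment extraction around repeats and the length/flank/GC filters that
# produce alignment references.

#' Extract a repeat-containing fragment with fixed flanks
#'
#' Trims the contig to the repeat plus at most `flank` bp on either side,
#' clipping at contig boundaries, and remaps the repeat coordinates into
#' fragment space.
#'
#' @param contig_seq DNA string of the source contig.
#' @param locus One row of an `ssr_loci` data.frame (list or data.frame with
#'   `locus_id`, `start`, `end`, `motif`, `n_units`, `contig`).
#' @param flank Maximum flank length in bp (default 250).
#' @return A list of class `ssr_fragment` with `locus_id`, `sequence`,
#'   `repeat_start`, `repeat_end` (1-based, inclusive, in fragment space),
#'   `motif`, `ref_units`, `source_contig`, `source_offset` (1-based start of
#'   the fragment on the contig).
#' @export
extract_fragment <- function(contig_seq, locus, flank = 250L) {
  n <- nchar(contig_seq)
  start <- as.integer(locus$start); end <- as.integer(locus$end)
  if (start < 1L || end > n || start > end) {
    stop("locus ", locus$locus_id, " does not lie within the contig")
  }
  frag_start <- max(1L, start - as.integer(flank))
  frag_end <- min(n, end + as.integer(flank))
  structure(list(
    locus_id = as.character(locus$locus_id),
    sequence = substr(contig_seq, frag_start, frag_end),
    repeat_start = start - frag_start + 1L,
    repeat_end = end - frag_start + 1L,
    motif = as.character(locus$motif),
    ref_units = as.integer(locus$n_units),
    source_contig = as.character(locus$contig),
    source_offset = frag_start), class = "ssr_fragment")
}

#' Extract fragments for a whole locus table
#'
#' @param sequences Named character vector (or `DNAStringSet`) of contigs.
#' @param loci `ssr_loci` data.frame.
#' @param flank Flank length in bp.
#' @return List of `ssr_fragment` objects, named by locus_id.
#' @export
extract_fragments <- function(sequences, loci, flank = 250L) {
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  frags <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    if (!locus$contig %in% names(sequences)) {
      stop("contig ", locus$contig, " not present in sequence set")
    }
    extract_fragment(sequences[[locus$contig]], locus, flank = flank)
  })
  names(frags) <- loci$locus_id
  frags
}

#' GC fraction of a DNA string
#' @param x Character vector of DNA strings.
#' @return Numeric vector of GC fractions (N excluded from the denominator).
#' @export
gc_fraction <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    ch <- ch[ch != "N"]
    if (length(ch) == 0) return(NA_real_)
    mean(ch %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

.fragment_flanks <- function(fragment) {
  list(left = substr(fragment$sequence, 1L, fragment$repeat_start - 1L),
       right = substr(fragment$sequence, fragment$repeat_end + 1L,
                      nchar(fragment$sequence)))
}

#' Filter fragments on length, flank sufficiency and flank GC content
#'
#' Fragments shorter than `min_length` are discarded; repeats too close to a
#' fragment end leave no room for a primer and are discarded; flanks with
#' very low GC content are unsuitable for primer design and are discarded
#' when `min_flank_gc` is non-`NULL`. Every rejection is tagged with its
#' (first applicable) reason.
#'
#' @param fragments List of `ssr_fragment` objects.
#' @param min_length Minimum fragment length in bp (default 400).
#' @param min_flank Minimum flank length in bp on each side (default 60,
#'   room for a 27 nt primer plus placement slack).
#' @param min_flank_gc Minimum GC fraction required of each flank (default
#'   0.20); set `NULL` to disable the GC screen.
#' @return List with `kept` (list of fragments) and `rejected` (data.frame
#'   `locus_id`, `reason` with reason in `too_short`, `flank_insufficient`,
#'   `low_gc_flank`).
#' @export
filter_fragments <- function(fragments, min_length = 400L, min_flank = 60L,
                             min_flank_gc = 0.20) {
  kept <- list(); rej_id <- character(); rej_reason <- character()
  for (fr in fragments) {
    flanks <- .fragment_flanks(fr)
    reason <- NULL
    if (nchar(fr$sequence) < min_length) {
      reason <- "too_short"
    } else if (nchar(flanks$left) < min_flank || nchar(flanks$right) < min_flank) {
      reason <- "flank_insufficient"
    } else if (!is.null(min_flank_gc)) {
      gc <- gc_fraction(c(flanks$left, flanks$right))
      if (any(gc < min_flank_gc, na.rm = TRUE)) reason <- "low_gc_flank"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1L]] <- fr
    } else {
      rej_id <- c(rej_id, fr$locus_id); rej_reason <- c(rej_reason, reason)
    }
  }
  names(kept) <- vapply(kept, `[[`, character(1), "locus_id")
  list(kept = kept,
       rejected = data.frame(locus_id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

#' Remove duplicate fragments (identical or reverse-complement sequence)
#'
#' Marker sets mined from fragmented assemblies contain fragments that are
#' exact duplicates or reverse complements of one another; only the first
#' occurrence (input order) is kept.
#'
#' @param fragments List of `ssr_fragment` objects.
#' @return List with `kept` and `duplicates` (data.frame `locus_id`,
#'   `duplicate_of`, `relation` in `identical`/`revcomp`).
#' @export
dedupe_fragments <- function(fragments) {
  seen <- character(); seen_id <- character()
  kept <- list(); dup_id <- character(); dup_of <- character(); rel <- character()
  for (fr in fragments) {
    s <- toupper(fr$sequence)
    hit <- match(s, seen)
    relation <- "identical"
    if (is.na(hit)) {
      hit <- match(revcomp(s), seen)
      relation <- "revcomp"
    }
    if (is.na(hit)) {
      kept[[length(kept) + 1L]] <- fr
      seen <- c(seen, s); seen_id <- c(seen_id, fr$locus_id)
    } else {
      dup_id <- c(dup_id, fr$locus_id); dup_of <- c(dup_of, seen_id[hit])
      rel <- c(rel, relation)
    }
  }
  names(kept) <- vapply(kept, `[[`, character(1), "locus_id")
  list(kept = kept,
       duplicates = data.frame(locus_id = dup_id, duplicate_of = dup_of,
                               relation = rel, stringsAsFactors = FALSE))
}

#' Write fragments as FASTA plus a TSV sidecar of repeat coordinates
#'
#' @param fragments List of `ssr_fragment` objects.
#' @param fasta_path Output FASTA path.
#' @param tsv_path Output TSV path (columns locus_id, repeat_start,
#'   repeat_end, motif, ref_units, source_contig, source_offset; 1-based
#'   inclusive coordinates).
#' @return Invisibly, the sidecar data.frame.
#' @export
write_fragments <- function(fragments, fasta_path, tsv_path) {
  seqs <- Biostrings::DNAStringSet(vapply(fragments, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(fragments, `[[`, character(1), "locus_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  side <- fragment_table(fragments)
  utils::write.table(side, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(side)
}

#' Tabular view of a fragment list
#' @param fragments List of `ssr_fragment` objects.
#' @return data.frame, one row per fragment.
#' @export
fragment_table <- function(fragments) {
  data.frame(
    locus_id = vapply(fragments, `[[`, character(1), "locus_id"),
    repeat_start = vapply(fragments, `[[`, integer(1), "repeat_start"),
    repeat_end = vapply(fragments, `[[`, integer(1), "repeat_end"),
    motif = vapply(fragments, `[[`, character(1), "motif"),
    ref_units = vapply(fragments, `[[`, integer(1), "ref_units"),
    source_contig = vapply(fragments, `[[`, character(1), "source_contig"),
    source_offset = vapply(fragments, `[[`, integer(1), "source_offset"),
    length = vapply(fragments, function(f) nchar(f$sequence), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read fragments back from FASTA + TSV sidecar
#' @param fasta_path FASTA of fragment sequences.
#' @param tsv_path TSV sidecar written by [write_fragments()].
#' @return List of `ssr_fragment` objects.
#' @export
read_fragments <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  side <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(motif = "character"))
  frags <- lapply(seq_len(nrow(side)), function(i) {
    row <- side[i, ]
    idx <- match(row$locus_id, names(seqs))
    if (is.na(idx)) stop("fragment ", row$locus_id, " missing from FASTA")
    structure(list(locus_id = row$locus_id,
                   sequence = as.character(seqs[[idx]]),
                   repeat_start = as.integer(row$repeat_start),
                   repeat_end = as.integer(row$repeat_end),
                   motif = row$motif, ref_units = as.integer(row$ref_units),
                   source_contig = row$source_contig,
                   source_offset = as.integer(row$source_offset)),
              class = "ssr_fragment")
  })
  names(frags) <- side$locus_id
  frags
}
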