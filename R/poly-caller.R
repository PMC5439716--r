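# Spanning-read repeat-unit genotyping and per-locus polymorphism calls.
#
# A read "spans" a repeat when it contains both flank anchors (the k bases
# of flank immediately adjacent to the repeat on each side). The number of
# repeat units in the read is the anchor-to-anchor gap divided by the motif
# length. This is a deterministic surrogate for visual inspection of
# alignments for "variation in number of repeat units but conserved
# flanking regions".

.anchor_starts <- function(anchor, reads, max_mismatch) {
  m <- Biostrings::vmatchPattern(anchor, reads, max.mismatch = max_mismatch,
                                 fixed = TRUE)
  Biostrings::startIndex(m)
}

# Vectorized spanning-read calls for one fragment. Returns a data.frame with
# one row per read that yields a call; reads without both anchors (or with
# ambiguous anchors) are dropped.
.spanning_calls <- function(read_seqs, read_ids, fragment, anchor_k = 15L,
                            max_anchor_mismatch = 1L) {
  p <- nchar(fragment$motif)
  if (fragment$repeat_start - 1L < anchor_k ||
      nchar(fragment$sequence) - fragment$repeat_end < anchor_k) {
    stop("fragment ", fragment$locus_id, " flanks shorter than anchor_k")
  }
  left_anchor <- substr(fragment$sequence, fragment$repeat_start - anchor_k,
                        fragment$repeat_start - 1L)
  right_anchor <- substr(fragment$sequence, fragment$repeat_end + 1L,
                         fragment$repeat_end + anchor_k)
  empty <- data.frame(locus_id = character(), read_id = character(),
                      strand = character(), units_observed = integer(),
                      non_integral = logical(), gap_bp = integer(),
                      left_anchor_pos = integer(), right_anchor_pos = integer(),
                      flank_mismatches = integer(), stringsAsFactors = FALSE)
  if (length(read_seqs) == 0) return(empty)
  reads_fwd <- Biostrings::DNAStringSet(toupper(read_seqs))
  reads_rev <- Biostrings::reverseComplement(reads_fwd)
  out <- vector("list", 2L)
  names(out) <- c("+", "-")
  taken <- rep(FALSE, length(read_seqs))
  for (strand in c("+", "-")) {
    reads <- if (strand == "+") reads_fwd else reads_rev
    ls <- .anchor_starts(left_anchor, reads, max_anchor_mismatch)
    rs <- .anchor_starts(right_anchor, reads, max_anchor_mismatch)
    rows <- list()
    widths <- Biostrings::width(reads)
    for (i in seq_along(read_seqs)) {
      if (taken[i]) next
      li <- ls[[i]]; ri <- rs[[i]]
      if (is.null(li) || is.null(ri)) next
      # drop matches hanging off the read ends
      li <- li[li >= 1L & li + nchar(left_anchor) - 1L <= widths[i]]
      ri <- ri[ri >= 1L & ri + nchar(right_anchor) - 1L <= widths[i]]
      if (length(li) != 1L || length(ri) != 1L) next  # absent or ambiguous
      left_end <- li + nchar(left_anchor) - 1L
      gap <- ri - left_end - 1L
      if (gap < 0L) next  # inconsistent anchor order
      units <- gap %/% p
      non_int <- (gap %% p) != 0L
      mm_left <- sum(strsplit(as.character(
        Biostrings::subseq(reads[[i]], li, left_end)), "")[[1]] !=
        strsplit(left_anchor, "")[[1]])
      mm_right <- sum(strsplit(as.character(
        Biostrings::subseq(reads[[i]], ri, ri + nchar(right_anchor) - 1L)),
        "")[[1]] != strsplit(right_anchor, "")[[1]])
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = fragment$locus_id, read_id = read_ids[i], strand = strand,
        units_observed = if (non_int) NA_integer_ else units,
        non_integral = non_int, gap_bp = gap,
        left_anchor_pos = li, right_anchor_pos = ri,
        flank_mismatches = mm_left + mm_right, stringsAsFactors = FALSE)
      taken[i] <- TRUE
    }
    out[[strand]] <- if (length(rows)) do.call(rbind, rows) else empty
  }
  res <- rbind(out[["+"]], out[["-"]])
  rownames(res) <- NULL
  res
}

#' Count repeat units in a single read spanning a repeat
#'
#' Locates the k-mer of flank immediately left of the repeat and the k-mer
#' immediately right of it (allowing up to `max_anchor_mismatch` mismatches
#' each) in the read or its reverse complement, and converts the
#' anchor-to-anchor gap into a repeat-unit count. A gap that is not a whole
#' number of motif units yields `units_observed = NA` and
#' `non_integral = TRUE`.
#'
#' @param read_seq DNA string of the read.
#' @param fragment `ssr_fragment` reference.
#' @param read_id Identifier recorded in the call.
#' @param anchor_k Anchor length in bp (default 15).
#' @param max_anchor_mismatch Mismatches tolerated per anchor (default 1).
#' @return A one-row data.frame (the spanning call), or `NULL` when the
#'   read does not span the repeat (missing or ambiguous anchor).
#' @export
count_units_in_read <- function(read_seq, fragment, read_id = "read",
                                anchor_k = 15L, max_anchor_mismatch = 1L) {
  calls <- .spanning_calls(read_seq, read_id, fragment, anchor_k,
                           max_anchor_mismatch)
  if (nrow(calls) == 0) NULL else calls[1, , drop = FALSE]
}

#' Classify a locus from its spanning-read calls
#'
#' A variant read is a spanning read whose observed unit count differs from
#' the reference. Non-integral anchor gaps are counted as variant evidence
#' only when at least `min_nonintegral_support` reads agree on the same gap
#' length (single non-integral reads are treated as indel sequencing noise).
#' Loci with reads aligned but fewer than `min_spanning` spanning reads, or
#' with more than `max_mapq0_fraction` of aligned reads at mapping quality
#' 0, are classed `poor_alignment`. A locus with variation in fewer than
#' `slight_threshold` of its reads is only `slightly_polymorphic`.
#'
#' @param calls data.frame of spanning calls (from [count_units_in_read()]
#'   rows or the pipeline).
#' @param ref_units Reference repeat-unit count.
#' @param n_aligned Number of reads aligned to the fragment.
#' @param min_spanning Minimum spanning reads required (default 8).
#' @param slight_threshold Variant fraction below which a polymorphic locus
#'   is only "slightly" polymorphic (default 0.02).
#' @param denominator Denominator of the variant fraction: `"spanning"`
#'   (default) or `"aligned"`.
#' @param mapq0_fraction Fraction of aligned reads with mapping quality 0
#'   (optional; `NA` disables the check).
#' @param max_mapq0_fraction Threshold on `mapq0_fraction` (default 0.5).
#' @param min_nonintegral_support Reads that must agree on a non-integral
#'   gap for it to count as variant evidence (default 2).
#' @return A list of class `locus_classification`: `locus_id`, `status`,
#'   `n_aligned_reads`, `n_spanning`, `n_variant`, `variant_fraction`,
#'   `unit_histogram` (named integer vector over observed unit counts).
#' @export
classify_locus <- function(calls, ref_units, n_aligned,
                           min_spanning = 8L, slight_threshold = 0.02,
                           denominator = c("spanning", "aligned"),
                           mapq0_fraction = NA_real_,
                           max_mapq0_fraction = 0.5,
                           min_nonintegral_support = 2L) {
  denominator <- match.arg(denominator)
  locus_id <- if (!is.null(calls) && nrow(calls)) calls$locus_id[1] else NA_character_
  n_spanning <- if (is.null(calls)) 0L else nrow(calls)
  integral <- if (n_spanning) calls[!calls$non_integral, , drop = FALSE] else calls
  hist <- integer()
  n_variant <- 0L
  if (n_spanning > 0) {
    if (nrow(integral)) {
      tab <- table(integral$units_observed)
      hist <- stats::setNames(as.integer(tab), names(tab))
      n_variant <- sum(integral$units_observed != ref_units)
    }
    ni <- calls[calls$non_integral, , drop = FALSE]
    if (nrow(ni)) {
      gap_tab <- table(ni$gap_bp)
      n_variant <- n_variant + sum(gap_tab[gap_tab >= min_nonintegral_support])
    }
  }
  denom <- if (denominator == "spanning") n_spanning else n_aligned
  vf <- if (denom > 0) n_variant / denom else NA_real_
  status <- if (n_aligned == 0) {
    "no_coverage"
  } else if (n_spanning < min_spanning ||
             (!is.na(mapq0_fraction) && mapq0_fraction > max_mapq0_fraction)) {
    "poor_alignment"
  } else if (n_variant == 0) {
    "not_polymorphic"
  } else if (vf < slight_threshold) {
    "slightly_polymorphic"
  } else {
    "clearly_polymorphic"
  }
  structure(list(locus_id = locus_id, status = status,
                 n_aligned_reads = as.integer(n_aligned),
                 n_spanning = n_spanning, n_variant = as.integer(n_variant),
                 variant_fraction = vf, unit_histogram = hist),
            class = "locus_classification")
}

#' Classify every fragment from reads grouped in memory
#'
#' @param reads_by_locus Named list (by locus_id) of character vectors of
#'   read sequences aligned to each fragment; loci absent from the list are
#'   reported as `no_coverage`.
#' @param fragments Named list of `ssr_fragment` objects.
#' @param mapq0_by_locus Optional named numeric vector of per-locus fractions
#'   of aligned reads at mapping quality 0.
#' @param ... Passed to [classify_locus()] and the spanning-call scan
#'   (`anchor_k`, `max_anchor_mismatch`, `min_spanning`, `slight_threshold`,
#'   ...).
#' @return data.frame of class `locus_classifications`, one row per
#'   fragment, with a `unit_histograms` attribute (named list).
#' @export
classify_loci <- function(reads_by_locus, fragments, anchor_k = 15L,
                          max_anchor_mismatch = 1L, mapq0_by_locus = NULL,
                          ...) {
  rows <- vector("list", length(fragments))
  hists <- vector("list", length(fragments))
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    reads <- reads_by_locus[[fr$locus_id]]
    if (is.null(reads)) reads <- character()
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("%s_read%05d", fr$locus_id, seq_along(reads))
    calls <- .spanning_calls(unname(reads), ids, fr, anchor_k, max_anchor_mismatch)
    mq0 <- NA_real_
    if (!is.null(mapq0_by_locus) && fr$locus_id %in% names(mapq0_by_locus)) {
      mq0 <- mapq0_by_locus[[fr$locus_id]]
    }
    cl <- classify_locus(calls, ref_units = fr$ref_units,
                         n_aligned = length(reads), mapq0_fraction = mq0, ...)
    rows[[i]] <- data.frame(
      locus_id = fr$locus_id, status = cl$status,
      n_aligned_reads = cl$n_aligned_reads, n_spanning = cl$n_spanning,
      n_variant = cl$n_variant, variant_fraction = cl$variant_fraction,
      stringsAsFactors = FALSE)
    hists[[i]] <- cl$unit_histogram
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  names(hists) <- res$locus_id
  attr(res, "unit_histograms") <- hists
  class(res) <- c("locus_classifications", "data.frame")
  res
}

#' Classify loci from a SAM/BAM alignment file
#'
#' Reads a standard SAM or BAM file of pooled-accession reads aligned to the
#' reference fragments and produces one classification per fragment,
#' including `no_coverage` entries for fragments without aligned reads.
#'
#' @param sam_path Path to a SAM or BAM file whose references are the
#'   fragment locus_ids.
#' @param fragments Named list of `ssr_fragment` objects.
#' @param ... Passed on to [classify_loci()].
#' @return `locus_classifications` data.frame.
#' @export
call_pipeline <- function(sam_path, fragments, ...) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam_path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  frag_ids <- vapply(fragments, `[[`, character(1), "locus_id")
  extra <- setdiff(names(header), frag_ids)
  if (length(extra) > 0) {
    stop("alignment references not present in fragment set: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "mapq", "seq"))
  recs <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- !bitwAnd(recs$flag, 4L)
  rname <- as.character(recs$rname)
  reads_by_locus <- list()
  mapq0 <- list()
  for (id in unique(rname[mapped])) {
    sel <- mapped & rname == id
    v <- as.character(recs$seq[sel])
    names(v) <- recs$qname[sel]
    reads_by_locus[[id]] <- v
    mapq0[[id]] <- mean(recs$mapq[sel] == 0, na.rm = TRUE)
  }
  classify_loci(reads_by_locus, fragments,
                mapq0_by_locus = unlist(mapq0), ...)
}
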