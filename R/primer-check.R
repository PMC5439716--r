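# Primer-placement feasibility screening. This is a triage, not a
# thermodynamic designer: windows are screened on length, GC content and a
# GC-based melting temperature estimate only.

#' Primer feasibility constraints
#'
#' @param primer_len_range Primer length bounds in nt (default 18-27).
#' @param target_tm Target annealing temperature in degrees C (default 60).
#' @param tm_tolerance Allowed deviation from `target_tm` (default 5).
#' @param product_size_range Expected PCR product size bounds in bp
#'   (default 90-400).
#' @param gc_range Allowed primer GC fraction bounds (default 0.30-0.70).
#' @return Object of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_len_range = c(18L, 27L),
                               target_tm = 60, tm_tolerance = 5,
                               product_size_range = c(90L, 400L),
                               gc_range = c(0.30, 0.70)) {
  stopifnot(primer_len_range[1] <= primer_len_range[2],
            product_size_range[1] <= product_size_range[2],
            gc_range[1] <= gc_range[2])
  structure(list(primer_len_range = as.integer(primer_len_range),
                 target_tm = target_tm, tm_tolerance = tm_tolerance,
                 product_size_range = as.integer(product_size_range),
                 gc_range = gc_range), class = "primer_constraints")
}

#' GC-based melting temperature estimate
#'
#' Tm = 64.9 + 41 * (nGC - 16.4) / length, the standard Wallace/Marmur-style
#' approximation for primers longer than ~14 nt.
#'
#' @param x Character vector of primer sequences.
#' @return Numeric vector of Tm estimates in degrees C.
#' @export
tm_gc <- function(x) {
  len <- nchar(x)
  ngc <- len * gc_fraction(x)
  64.9 + 41 * (ngc - 16.4) / len
}

# All windows of lengths in len_range within [lo, hi] of the fragment that
# satisfy GC and Tm bounds. Returns data.frame(start, end, gc, tm).
.feasible_windows <- function(sequence, lo, hi, constraints) {
  rows <- list()
  for (len in seq(constraints$primer_len_range[1], constraints$primer_len_range[2])) {
    if (hi - lo + 1L < len) next
    starts <- seq.int(lo, hi - len + 1L)
    win <- substring(sequence, starts, starts + len - 1L)
    gc <- gc_fraction(win)
    tm <- tm_gc(win)
    ok <- !is.na(gc) & gc >= constraints$gc_range[1] & gc <= constraints$gc_range[2] &
      abs(tm - constraints$target_tm) <= constraints$tm_tolerance &
      !grepl("N", win, fixed = TRUE)
    if (any(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = starts[ok], end = starts[ok] + len - 1L,
        gc = gc[ok], tm = tm[ok])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      gc = numeric(), tm = numeric()))
  }
  do.call(rbind, rows)
}

#' Enumerate feasible primer-window pairs for a fragment
#'
#' Finds all (forward, reverse) primer windows in the flanks that satisfy
#' the length, GC and Tm constraints, paired so that the product (from the
#' start of the forward window to the end of the reverse window) contains
#' the full repeat and has a size within the configured range. The reverse
#' window is reported in fragment coordinates; the actual reverse primer is
#' its reverse complement.
#'
#' @param fragment `ssr_fragment` object.
#' @param constraints [primer_constraints()] object.
#' @return data.frame with columns `left_start`, `left_end`, `right_start`,
#'   `right_end`, `product_size`, `left_tm`, `right_tm`, `left_gc`,
#'   `right_gc`, ordered deterministically (left_start, right_start). Empty
#'   when no pair is feasible (the locus is flagged, not dropped).
#' @export
feasible_primer_windows <- function(fragment,
                                    constraints = primer_constraints()) {
  seqlen <- nchar(fragment$sequence)
  left <- .feasible_windows(fragment$sequence, 1L, fragment$repeat_start - 1L,
                            constraints)
  right <- .feasible_windows(fragment$sequence, fragment$repeat_end + 1L,
                             seqlen, constraints)
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      product_size = integer(), left_tm = numeric(),
                      right_tm = numeric(), left_gc = numeric(),
                      right_gc = numeric())
  if (nrow(left) == 0 || nrow(right) == 0) return(empty)
  pairs <- expand.grid(li = seq_len(nrow(left)), ri = seq_len(nrow(right)))
  size <- right$end[pairs$ri] - left$start[pairs$li] + 1L
  ok <- size >= constraints$product_size_range[1] &
    size <= constraints$product_size_range[2]
  if (!any(ok)) return(empty)
  pairs <- pairs[ok, , drop = FALSE]
  res <- data.frame(
    left_start = left$start[pairs$li], left_end = left$end[pairs$li],
    right_start = right$start[pairs$ri], right_end = right$end[pairs$ri],
    product_size = size[ok],
    left_tm = left$tm[pairs$li], right_tm = right$tm[pairs$ri],
    left_gc = left$gc[pairs$li], right_gc = right$gc[pairs$ri])
  res <- res[order(res$left_start, res$right_start, res$left_end, res$right_end), ]
  rownames(res) <- NULL
  res
}

#' Screen a fragment set for primer feasibility
#'
#' @param fragments Named list of `ssr_fragment` objects.
#' @param constraints [primer_constraints()] object.
#' @return data.frame with one row per fragment: `locus_id`, `feasible`
#'   (logical), `n_pairs`, and the coordinates of the first feasible pair
#'   (NA when none). Pair counts are computed without materializing every
#'   pair, so large flank window sets stay cheap.
#' @export
primer_feasibility <- function(fragments, constraints = primer_constraints()) {
  rows <- lapply(fragments, function(fr) {
    seqlen <- nchar(fr$sequence)
    left <- .feasible_windows(fr$sequence, 1L, fr$repeat_start - 1L, constraints)
    right <- .feasible_windows(fr$sequence, fr$repeat_end + 1L, seqlen,
                               constraints)
    na_row <- data.frame(locus_id = fr$locus_id, feasible = FALSE, n_pairs = 0L,
                         left_start = NA_integer_, left_end = NA_integer_,
                         right_start = NA_integer_, right_end = NA_integer_,
                         product_size = NA_integer_, stringsAsFactors = FALSE)
    if (nrow(left) == 0 || nrow(right) == 0) return(na_row)
    re_sorted <- sort(right$end)
    lo <- left$start + constraints$product_size_range[1] - 1L
    hi <- left$start + constraints$product_size_range[2] - 1L
    cnt <- findInterval(hi, re_sorted) - findInterval(lo - 1L, re_sorted)
    n_pairs <- sum(cnt)
    if (n_pairs == 0) return(na_row)
    ord <- order(left$start, left$end)
    li <- ord[which(cnt[ord] > 0)[1]]
    cand <- which(right$end >= lo[li] & right$end <= hi[li])
    ri <- cand[order(right$start[cand], right$end[cand])][1]
    data.frame(locus_id = fr$locus_id, feasible = TRUE, n_pairs = n_pairs,
               left_start = left$start[li], left_end = left$end[li],
               right_start = right$start[ri], right_end = right$end[ri],
               product_size = right$end[ri] - left$start[li] + 1L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
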