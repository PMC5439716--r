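# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force maximal-perfect-repeat oracle. Independent formulation from
# the package's shifted-character run detector: it compares whole motif
# blocks at stride p (chained right-to-left), anchors each repeat at the
# leftmost character of its run, and checks motif primitivity by explicit
# division. Returns a data.frame sorted like find_perfect_repeats.
oracle_find_repeats <- function(sequence, config = ssr_search_config()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- list()
  for (p in config$motif_lengths) {
    minu <- config$min_units[[as.character(p)]]
    if (n < p * minu) next
    nb <- n - p + 1L
    blocks <- substring(sequence, seq_len(nb), seq_len(nb) + p - 1L)
    valid <- !grepl("N", blocks, fixed = TRUE)
    u <- integer(nb)
    for (i in rev(seq_len(nb))) {
      if (!valid[i]) { u[i] <- 0L; next }
      nxt <- i + p
      u[i] <- if (nxt <= nb && valid[nxt] && blocks[nxt] == blocks[i])
        u[nxt] + 1L else 1L
    }
    for (i in seq_len(nb)) {
      if (u[i] < minu) next
      # leftmost character of the run: the char one left must not pair
      if (i > 1L && chars[i - 1L] != "N" && chars[i - 1L] == chars[i + p - 1L]) next
      motif <- blocks[i]
      primitive <- TRUE
      if (p > 1L) {
        for (q in seq_len(p - 1L)) {
          if (p %% q == 0L &&
              paste(rep(substr(motif, 1L, q), p %/% q), collapse = "") == motif) {
            primitive <- FALSE; break
          }
        }
      }
      if (!primitive) next
      out[[length(out) + 1L]] <- data.frame(
        start = i, end = i + u[i] * p - 1L, motif = motif, n_units = u[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      n_units = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, nchar(res$motif)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Botstein PIC by explicit double loop over allele pairs.
oracle_pic <- function(p) {
  s <- 1 - sum(p^2)
  k <- length(p)
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) s <- s - 2 * p[i]^2 * p[j]^2
  }
  s
}

random_simplex <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# A fragment with known flanks around a perfect repeat.
toy_fragment <- function(left, motif, units, right, locus_id = "toy") {
  structure(list(
    locus_id = locus_id,
    sequence = paste0(left, strrep(motif, units), right),
    repeat_start = nchar(left) + 1L,
    repeat_end = as.integer(nchar(left) + units * nchar(motif)),
    motif = motif, ref_units = as.integer(units),
    source_contig = "toy_contig", source_offset = 1L),
    class = "ssr_fragment")
}

# Reads guaranteed to span the repeat: windows of the (possibly variant)
# haplotype that contain both anchors plus margin.
spanning_read <- function(fragment, units, margin = 25L) {
  hap <- paste0(substr(fragment$sequence, 1L, fragment$repeat_start - 1L),
                strrep(fragment$motif, units),
                substr(fragment$sequence, fragment$repeat_end + 1L,
                       nchar(fragment$sequence)))
  start <- fragment$repeat_start - margin
  end <- fragment$repeat_start + units * nchar(fragment$motif) + margin - 1L
  substr(hap, start, end)
}

# Small genotype table from explicit allele-pair strings like "155/158",
# "." for missing; rows = loci, columns = accessions.
gt_from_strings <- function(cells, loci = NULL, accessions = NULL) {
  m <- as.matrix(cells)
  a1 <- matrix(NA_integer_, nrow(m), ncol(m))
  a2 <- matrix(NA_integer_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- m[i, j]
    if (v == ".") next
    parts <- as.integer(strsplit(v, "/", fixed = TRUE)[[1]])
    if (length(parts) == 1) parts <- c(parts, parts)
    a1[i, j] <- parts[1]; a2[i, j] <- parts[2]
  }
  genotype_table(a1, a2,
                 loci = loci %||% sprintf("L%02d", seq_len(nrow(m))),
                 accessions = accessions %||% sprintf("A%02d", seq_len(ncol(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
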