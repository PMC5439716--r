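# Readers/writers and the umbrella funnel that ties the stages together:
# find -> AT-removal -> extract/filter -> classify -> primer feasibility.

#' Read a (possibly gzipped) FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  s <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write an `ssr_loci` table as TSV (1-based inclusive coordinates)
#' @param loci `ssr_loci` data.frame.
#' @param path Output path.
#' @export
write_loci <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an `ssr_loci` table written by [write_loci()]
#' @param path TSV path.
#' @return `ssr_loci` data.frame.
#' @export
read_loci <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(motif = "character",
                                         canonical_motif = "character"))
  class(df) <- c("ssr_loci", "data.frame")
  df
}

#' Run the marker-discovery funnel
#'
#' Executes the stepwise reduction used for in-silico SSR marker mining:
#' repeat detection, removal of A/T-only motifs, fragment extraction with
#' fixed flanks, length/flank/GC filtering, duplicate removal,
#' polymorphism classification from aligned reads, and primer feasibility
#' for the clearly polymorphic loci. Category counts are returned as a
#' self-consistent report.
#'
#' @param sequences Named character vector of contigs (or a FASTA path).
#' @param reads Either a named list of read vectors keyed by locus_id, a
#'   SAM/BAM path, or `NULL` to stop after the fragment filters.
#' @param config `ssr_search_config` for the detection stage.
#' @param flank,min_length,min_flank,min_flank_gc Fragment extraction and
#'   filter settings (see [filter_fragments()]).
#' @param dedupe Remove identical / reverse-complement duplicate fragments
#'   (default TRUE).
#' @param constraints `primer_constraints` for the feasibility stage.
#' @param out_dir Optional directory for stage outputs (loci TSV, fragment
#'   FASTA/TSV, classification TSV, feasibility TSV).
#' @param ... Passed to the classification stage ([classify_loci()] /
#'   [call_pipeline()]).
#' @return List of class `funnel_report`: `counts` (named integer vector:
#'   input_loci, after_at_removal, after_fragment_filters, no_coverage,
#'   poor_alignment, not_polymorphic, slightly_polymorphic,
#'   clearly_polymorphic, primer_feasible), plus `loci`, `fragments`,
#'   `rejected`, `duplicates`, `classification`, `feasibility`.
#' @export
run_funnel <- function(sequences, reads = NULL, config = ssr_search_config(),
                       flank = 250L, min_length = 400L, min_flank = 60L,
                       min_flank_gc = 0.20, dedupe = TRUE,
                       constraints = primer_constraints(), out_dir = NULL,
                       ...) {
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  loci <- find_repeats_in_genome(sequences, config)
  n_input <- nrow(loci)
  loci_kept <- loci[!is_at_only(loci$motif), , drop = FALSE]
  n_after_at <- nrow(loci_kept)
  frags <- extract_fragments(sequences, loci_kept, flank = flank)
  filt <- filter_fragments(frags, min_length = min_length,
                           min_flank = min_flank, min_flank_gc = min_flank_gc)
  dups <- data.frame(locus_id = character(), duplicate_of = character(),
                     relation = character(), stringsAsFactors = FALSE)
  kept <- filt$kept
  if (dedupe) {
    dd <- dedupe_fragments(kept)
    kept <- dd$kept
    dups <- dd$duplicates
  }
  n_after_filters <- length(kept)
  classification <- NULL
  feasibility <- NULL
  counts <- c(input_loci = n_input, after_at_removal = n_after_at,
              after_fragment_filters = n_after_filters)
  if (!is.null(reads)) {
    classification <- if (is.character(reads)) {
      call_pipeline(reads, kept, ...)
    } else {
      classify_loci(reads, kept, ...)
    }
    tab <- table(factor(classification$status,
                        levels = c("no_coverage", "poor_alignment",
                                   "not_polymorphic", "slightly_polymorphic",
                                   "clearly_polymorphic")))
    counts <- c(counts, stats::setNames(as.integer(tab), names(tab)))
    clear <- classification$locus_id[classification$status == "clearly_polymorphic"]
    feasibility <- primer_feasibility(kept[clear], constraints)
    counts <- c(counts, primer_feasible = sum(feasibility$feasible))
  }
  report <- structure(list(counts = counts, loci = loci, fragments = kept,
                           rejected = filt$rejected, duplicates = dups,
                           classification = classification,
                           feasibility = feasibility),
                      class = "funnel_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_loci(loci, file.path(out_dir, "loci.tsv"))
    write_fragments(kept, file.path(out_dir, "fragments.fasta"),
                    file.path(out_dir, "fragments.tsv"))
    if (!is.null(classification)) {
      utils::write.table(as.data.frame(classification),
                         file.path(out_dir, "classification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(feasibility)) {
      utils::write.table(feasibility, file.path(out_dir, "feasibility.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("SSR marker-discovery funnel\n")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
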