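# Binary encoding of SSR genotypes, genetic distances, and NJ/UPGMA
# dendrograms with Newick output. Tree construction is delegated to the
# standard phylogenetics stack (ape, phangorn); the encoding and distance
# definitions live here.

#' Convert a genotype table to a binary allele-presence matrix
#'
#' One column per observed (locus, allele) combination, ordered by locus
#' (table order) then allele size ascending; entry 1 iff the accession
#' carries the allele. Missing calls produce an all-zero block for that
#' locus; the affected (accession, locus) pairs are recorded in the
#' `missing_blocks` attribute.
#'
#' @param table `genotype_table`.
#' @return Integer matrix (accessions x columns) with column names
#'   `"<locus>:<allele>"`, a `loci` attribute giving each column's locus,
#'   and a `missing_blocks` attribute (data.frame accession, locus).
#' @export
to_binary <- function(table) {
  cols <- list(); col_locus <- character(); col_names <- character()
  miss_acc <- character(); miss_locus <- character()
  for (locus in table$loci) {
    i <- match(locus, table$loci)
    a1 <- table$allele1[i, ]; a2 <- table$allele2[i, ]
    alleles <- sort(unique(c(a1, a2)))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) next
    for (al in alleles) {
      cols[[length(cols) + 1L]] <- as.integer(!is.na(a1) & (a1 == al | a2 == al))
      col_locus <- c(col_locus, locus)
      col_names <- c(col_names, paste0(locus, ":", al))
    }
    missing <- is.na(a1)
    if (any(missing)) {
      miss_acc <- c(miss_acc, table$accessions[missing])
      miss_locus <- c(miss_locus, rep(locus, sum(missing)))
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- table$accessions
  colnames(m) <- col_names
  attr(m, "loci") <- col_locus
  attr(m, "missing_blocks") <- data.frame(accession = miss_acc,
                                          locus = miss_locus,
                                          stringsAsFactors = FALSE)
  m
}

#' Pairwise genetic distances between accessions
#'
#' Three standard options over the binary allele-presence encoding:
#' \describe{
#'   \item{simple_matching}{fraction of mismatched columns among columns
#'     scored (non-missing locus blocks) in both accessions.}
#'   \item{dice}{1 - 2|A intersect B| / (|A| + |B|) over the allele sets of
#'     the two accessions.}
#'   \item{shared_allele}{1 minus the per-locus Dice share
#'     2|A_l intersect B_l| / (|A_l| + |B_l|), averaged over loci scored in
#'     both accessions.}
#' }
#'
#' @param binary Matrix from [to_binary()].
#' @param method One of `"shared_allele"` (default), `"simple_matching"`,
#'   `"dice"`.
#' @return Symmetric `dist`-convertible matrix with zero diagonal.
#' @export
distance_matrix <- function(binary,
                            method = c("shared_allele", "simple_matching", "dice")) {
  method <- match.arg(method)
  n <- nrow(binary)
  if (n < 2) stop("need at least two accessions")
  col_locus <- attr(binary, "loci")
  if (is.null(col_locus)) col_locus <- rep("all", ncol(binary))
  # per-accession per-locus scoring: a locus block is scored when it has
  # at least one 1 (all-zero block = missing call)
  loci <- unique(col_locus)
  block_cols <- lapply(loci, function(l) which(col_locus == l))
  scored <- vapply(block_cols, function(cc) {
    rowSums(binary[, cc, drop = FALSE]) > 0
  }, logical(n))  # n x loci
  if (is.null(dim(scored))) scored <- matrix(scored, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(binary), rownames(binary)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- scored[i, ] & scored[j, ]
      if (!any(both)) { d[i, j] <- d[j, i] <- NA_real_; next }
      use_cols <- unlist(block_cols[both])
      xi <- binary[i, use_cols]; xj <- binary[j, use_cols]
      val <- switch(method,
        simple_matching = mean(xi != xj),
        dice = {
          inter <- sum(xi == 1 & xj == 1)
          1 - 2 * inter / (sum(xi) + sum(xj))
        },
        shared_allele = {
          per_locus <- vapply(which(both), function(li) {
            cc <- block_cols[[li]]
            ai <- binary[i, cc]; aj <- binary[j, cc]
            2 * sum(ai == 1 & aj == 1) / (sum(ai) + sum(aj))
          }, numeric(1))
          1 - mean(per_locus)
        })
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`). On additive distances the
#' tree's path lengths reproduce the input exactly. Negative branch lengths
#' can arise on non-additive input and are kept unless `clamp = TRUE`.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist`.
#' @param clamp Clamp negative branch lengths to zero (default FALSE).
#' @return `ape::phylo` unrooted tree.
#' @export
neighbor_joining <- function(d, clamp = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  if (clamp) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering returning a rooted ultrametric
#' tree (via `phangorn::upgma`); ties in the minimum distance are resolved
#' deterministically by the clustering order of `hclust`.
#'
#' @param d Symmetric distance matrix (>= 2 taxa) or `dist`.
#' @return `ape::phylo` rooted ultrametric tree.
#' @export
upgma_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("UPGMA needs at least 2 taxa")
  phangorn::upgma(stats::as.dist(d))
}

#' Build a dendrogram straight from a genotype table
#'
#' Convenience wrapper: binary encoding, distance, tree, optional Newick
#' output.
#'
#' @param table `genotype_table`.
#' @param method Tree method, `"nj"` or `"upgma"`.
#' @param distance Distance method (see [distance_matrix()]).
#' @param newick_path Optional path to write the Newick tree.
#' @return `ape::phylo` tree.
#' @export
genotype_tree <- function(table, method = c("nj", "upgma"),
                          distance = "shared_allele", newick_path = NULL) {
  method <- match.arg(method)
  d <- distance_matrix(to_binary(table), method = distance)
  if (any(is.na(d))) stop("distance undefined for some accession pair (no shared scored loci)")
  tr <- if (method == "nj") neighbor_joining(d) else upgma_tree(d)
  if (!is.null(newick_path)) ape::write.tree(tr, file = newick_path)
  tr
}

#' Write a square PHYLIP distance matrix
#' @param d Symmetric distance matrix with row names.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(substr(rownames(d)[i], 1, 10), width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
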