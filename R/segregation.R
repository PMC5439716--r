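# Mendelian segregation bookkeeping for a two-way pseudo-testcross mapping
# population: expected class from the parental genotypes, chi-square
# goodness of fit of the seedling counts.

SEGREGATION_CLASSES <- c("1:1_female", "1:1_male", "1:1:1:1", "1:2:1", "none")

.expected_proportions <- list(
  "1:1_female" = c(0.5, 0.5),
  "1:1_male"   = c(0.5, 0.5),
  "1:1:1:1"    = rep(0.25, 4),
  "1:2:1"      = c(0.25, 0.5, 0.25))

#' Expected segregation class from parental genotypes
#'
#' For a cross between outbred diploid parents, a locus heterozygous in
#' both parents for the same two alleles segregates 1:2:1; heterozygous in
#' both parents with different allele pairs (sharing at most one allele)
#' segregates 1:1:1:1; heterozygous in only one parent segregates 1:1 from
#' that parent; homozygous in both parents does not segregate. Null alleles
#' are not modelled.
#'
#' @param female,male Length-2 vectors of parental allele sizes.
#' @return One of `"1:2:1"`, `"1:1:1:1"`, `"1:1_female"`, `"1:1_male"`,
#'   `"none"`.
#' @export
expected_class <- function(female, male) {
  if (length(female) != 2 || length(male) != 2 ||
      any(is.na(female)) || any(is.na(male))) {
    stop("both parents need a complete two-allele genotype")
  }
  f_het <- female[1] != female[2]
  m_het <- male[1] != male[2]
  if (f_het && m_het) {
    if (setequal(female, male)) "1:2:1" else "1:1:1:1"
  } else if (f_het) {
    "1:1_female"
  } else if (m_het) {
    "1:1_male"
  } else {
    "none"
  }
}

#' Chi-square goodness of fit to an expected segregation ratio
#'
#' Pearson chi-square of observed genotype-class counts against the
#' expected proportions of the class, without continuity correction;
#' df = number of classes - 1.
#'
#' @param observed_counts Integer vector of per-class seedling counts (2
#'   classes for 1:1, 3 for 1:2:1 in the order low/het/high, 4 for
#'   1:1:1:1).
#' @param expected_class One of the segregation classes (not `"none"`).
#' @return List with `chi2`, `df`, `p_value`.
#' @export
chi_square_fit <- function(observed_counts, expected_class) {
  if (!expected_class %in% names(.expected_proportions)) {
    stop("no expected ratio for class '", expected_class, "'")
  }
  p <- .expected_proportions[[expected_class]]
  if (length(observed_counts) != length(p)) {
    stop("expected ", length(p), " count classes for ratio ", expected_class)
  }
  if (any(observed_counts < 0) || sum(observed_counts) == 0) {
    stop("counts must be nonnegative with positive total")
  }
  ht <- suppressWarnings(stats::chisq.test(observed_counts, p = p, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Segregation tests for a table of loci
#'
#' @param seg data.frame with columns `locus`, `female1`, `female2`,
#'   `male1`, `male2`, and count columns `n1`..`n4` (unused classes NA or
#'   absent).
#' @return Input data.frame with `class`, `chi2`, `df`, `p_value` appended;
#'   loci with class `"none"` get NA statistics.
#' @export
segregation_test <- function(seg) {
  res <- seg
  res$class <- NA_character_
  res$chi2 <- NA_real_; res$df <- NA_integer_; res$p_value <- NA_real_
  count_cols <- intersect(c("n1", "n2", "n3", "n4"), names(seg))
  for (i in seq_len(nrow(seg))) {
    cls <- expected_class(c(seg$female1[i], seg$female2[i]),
                          c(seg$male1[i], seg$male2[i]))
    res$class[i] <- cls
    if (cls == "none") next
    counts <- as.numeric(seg[i, count_cols])
    counts <- counts[!is.na(counts)]
    fit <- chi_square_fit(counts, cls)
    res$chi2[i] <- fit$chi2; res$df[i] <- fit$df; res$p_value[i] <- fit$p_value
  }
  res
}

#' Per-allele transmission frequencies from a heterozygous parent
#'
#' Reports how often each parental allele was transmitted, as a screen for
#' distorted transmission; no model is fitted.
#'
#' @param parent Length-2 vector of parental alleles (heterozygous).
#' @param transmitted Vector of alleles observed to be inherited from this
#'   parent across seedlings.
#' @return data.frame `allele`, `count`, `frequency`.
#' @export
transmission_frequencies <- function(parent, transmitted) {
  if (parent[1] == parent[2]) stop("parent is homozygous; nothing to compare")
  if (!all(transmitted %in% parent)) stop("transmitted alleles not in parent genotype")
  counts <- vapply(parent, function(a) sum(transmitted == a), numeric(1))
  data.frame(allele = parent, count = as.integer(counts),
             frequency = counts / sum(counts), row.names = NULL)
}
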