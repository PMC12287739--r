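#' Genotype counts at a biallelic locus
#'
#' @param n_homo_ref,n_het,n_homo_alt,n_missing Non-negative integer counts of
#'   the three genotype classes and of untyped samples.
#' @return An object of class `"genotype_counts"`.
#' @examples
#' genotype_counts(209, 147, 28)   # LIFR c.*127T>C in small-tailed Han sheep
#' @export
genotype_counts <- function(n_homo_ref, n_het, n_homo_alt, n_missing = 0) {
  x <- c(n_homo_ref, n_het, n_homo_alt, n_missing)
  if (any(x < 0) || any(x != round(x)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  structure(list(n_homo_ref = n_homo_ref, n_het = n_het,
                 n_homo_alt = n_homo_alt, n_missing = n_missing),
            class = "genotype_counts")
}

n_typed <- function(counts)
  counts$n_homo_ref + counts$n_het + counts$n_homo_alt

#' Tally genotype calls for one locus
#'
#' Missing calls never enter a statistic: they are tallied separately and
#' shrink the typed sample size.
#'
#' @param mat A [genotype_matrix()].
#' @param locus_id Locus column to tally.
#' @param samples Optional subset of sample ids (e.g. one breed).
#' @return A [genotype_counts()].
#' @export
count_genotypes <- function(mat, locus_id, samples = NULL) {
  if (!locus_id %in% names(mat$loci))
    stop("unknown locus '", locus_id, "'", call. = FALSE)
  calls <- mat$calls[, locus_id]
  if (!is.null(samples)) calls <- calls[mat$samples %in% samples]
  lv <- genotype_levels(mat$loci[[locus_id]])
  genotype_counts(sum(calls == lv[1L], na.rm = TRUE),
                  sum(calls == lv[2L], na.rm = TRUE),
                  sum(calls == lv[3L], na.rm = TRUE),
                  sum(is.na(calls)))
}

#' Allele frequencies from genotype counts
#'
#' By gene counting: the reference-allele frequency is
#' (2 n_homo_ref + n_het) / (2 n_typed).
#'
#' @param counts A [genotype_counts()] with at least one typed sample.
#' @return Numeric vector `c(p_ref, p_alt)` summing to one.
#' @export
allele_frequencies <- function(counts) {
  nt <- n_typed(counts)
  if (nt < 1) stop("no typed samples: allele frequencies undefined",
                   call. = FALSE)
  p <- (2 * counts$n_homo_ref + counts$n_het) / (2 * nt)
  c(p_ref = p, p_alt = 1 - p)
}

check_freqs <- function(p) {
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-12)
    stop("allele frequencies must lie in [0,1] and sum to 1", call. = FALSE)
  p
}

#' Polymorphism information content
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2, the classic marker
#' informativeness measure. For a biallelic locus its maximum is 0.375 at
#' p = 0.5.
#'
#' @param p Vector of allele frequencies (sums to one).
#' @return PIC in \[0, 1\].
#' @export
pic <- function(p) {
  check_freqs(p)
  cross <- 0
  n <- length(p)
  if (n > 1)
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        cross <- cross + 2 * p[i]^2 * p[j]^2
  unname(1 - sum(p^2) - cross)
}

#' Expected heterozygosity (gene diversity)
#'
#' He = 1 - sum(p_i^2), the heterozygote proportion expected under random
#' mating.
#'
#' @inheritParams pic
#' @return He in \[0, 1\].
#' @export
expected_heterozygosity <- function(p) {
  check_freqs(p)
  unname(1 - sum(p^2))
}

#' Effective number of alleles
#'
#' Ne = 1 / sum(p_i^2): the number of equally frequent alleles giving the same
#' expected homozygosity.
#'
#' @inheritParams pic
#' @return Ne in \[1, number of alleles\].
#' @export
effective_allele_number <- function(p) {
  check_freqs(p)
  unname(1 / sum(p^2))
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Compares observed genotype counts with the Hardy-Weinberg expectations
#' n(p^2, 2pq, q^2) at the observed allele frequencies. One degree of freedom
#' (three classes, one estimated frequency); no continuity correction. A
#' monomorphic locus is in equilibrium by definition: chi2 = 0, p = 1. Cells
#' with zero expectation (p or q exactly 0) contribute nothing.
#'
#' @param counts A [genotype_counts()].
#' @return List with `chi2`, `p`, `df`, and the `expected` class counts.
#' @export
hwe_chi_square <- function(counts) {
  nt <- n_typed(counts)
  if (nt < 1) stop("no typed samples: HWE test undefined", call. = FALSE)
  p <- allele_frequencies(counts)[1L]
  q <- 1 - p
  expected <- nt * c(p^2, 2 * p * q, q^2)
  observed <- c(counts$n_homo_ref, counts$n_het, counts$n_homo_alt)
  nz <- expected > 0
  chi2 <- sum((observed[nz] - expected[nz])^2 / expected[nz])
  if (p == 0 || p == 1) chi2 <- 0   # monomorphic: equilibrium by definition
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, expected = unname(expected))
}

#' Classify marker polymorphism from PIC
#'
#' Standard cutoffs: low below 0.25, moderate in \[0.25, 0.5), high at or
#' above 0.5.
#'
#' @param pic_value PIC in \[0, 1\].
#' @return `"low"`, `"moderate"` or `"high"` (vectorised).
#' @export
classify_polymorphism <- function(pic_value) {
  stopifnot(all(pic_value >= 0 & pic_value <= 1))
  out <- ifelse(pic_value < 0.25, "low",
                ifelse(pic_value < 0.5, "moderate", "high"))
  out
}

summary_row <- function(counts, loc, breed) {
  nt <- n_typed(counts)
  p <- allele_frequencies(counts)
  hwe <- hwe_chi_square(counts)
  pic_v <- pic(p)
  data.frame(
    breed = breed, gene = loc$gene, locus = loc$id,
    n_typed = nt, n_missing = counts$n_missing,
    geno_homo_ref = counts$n_homo_ref / nt,
    geno_het = counts$n_het / nt,
    geno_homo_alt = counts$n_homo_alt / nt,
    freq_ref = unname(p[1L]), freq_alt = unname(p[2L]),
    pic = pic_v, he = expected_heterozygosity(p),
    ne = effective_allele_number(p),
    hwe_chi2 = hwe$chi2, hwe_p = hwe$p,
    polymorphism = classify_polymorphism(pic_v),
    stringsAsFactors = FALSE)
}

#' Per-breed, per-locus population-genetic summary
#'
#' One row per breed x locus with genotype and allele frequencies, PIC, He,
#' Ne, the Hardy-Weinberg chi-square p-value and the polymorphism class. All
#' values are full precision; [report_polymorphism()] rounds for display.
#'
#' @param mat A [genotype_matrix()].
#' @param meta Optional metadata data.frame (see [read_sample_meta()]); when
#'   supplied, summaries are computed within each breed, otherwise over all
#'   samples with breed `"all"`.
#' @param breeds Optional subset of breeds to summarise.
#' @return A data.frame, one row per breed x locus.
#' @export
locus_summary <- function(mat, meta = NULL, breeds = NULL) {
  if (is.null(meta)) {
    groups <- list(all = mat$samples)
  } else {
    meta <- meta[meta$sample_id %in% mat$samples, ]
    groups <- split(meta$sample_id, meta$breed)
    if (!is.null(breeds)) {
      missing_b <- setdiff(breeds, names(groups))
      if (length(missing_b))
        warning("breed(s) with zero samples: ",
                paste(missing_b, collapse = ", "), call. = FALSE)
      groups <- groups[intersect(breeds, names(groups))]
    }
  }
  rows <- list()
  for (b in names(groups))
    for (loc in mat$loci)
      rows[[length(rows) + 1L]] <-
        summary_row(count_genotypes(mat, loc$id, groups[[b]]), loc, b)
  if (!length(rows))
    return(data.frame())
  do.call(rbind, rows)
}
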