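#' Allele counts from genotype counts
#'
#' Gene counting: each homozygote carries two copies, each heterozygote one
#' of each.
#'
#' @param counts A [genotype_counts()].
#' @return Integer vector `c(n_ref, n_alt)`.
#' @export
allele_counts_from_genotypes <- function(counts) {
  c(n_ref = 2 * counts$n_homo_ref + counts$n_het,
    n_alt = 2 * counts$n_homo_alt + counts$n_het)
}

# run an expression with a locally seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Pearson chi-square test on a group x category count table
#'
#' Used for both the 2 x 3 genotype table and the 2 x 2 allele table between
#' fecundity groups. No continuity correction. Empty categories (zero column
#' totals) are dropped and the degrees of freedom adjusted. When any expected
#' cell is below 5 a warning is issued and a Monte Carlo p-value (10,000
#' simulated tables, fixed internal seed) is reported alongside; the
#' asymptotic p remains the primary value.
#'
#' @param tab Numeric matrix of counts, groups in rows.
#' @return List with `chi2`, `p`, `df`, `mc_p` (`NA` unless expected cells
#'   were small) and `expected`.
#' @export
contingency_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0))
    stop("a group has zero typed samples: test undefined", call. = FALSE)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L)
    return(list(chi2 = 0, p = 1, df = 0L, mc_p = NA_real_,
                expected = tab))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  mc_p <- NA_real_
  if (any(ct$expected < 5)) {
    warning("expected cell count < 5; Monte Carlo p-value also reported",
            call. = FALSE)
    mc <- with_local_seed(1905L, suppressWarnings(
      stats::chisq.test(tab, simulate.p.value = TRUE, B = 10000L)))
    mc_p <- unname(mc$p.value)
  }
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
       df = unname(ct$parameter), mc_p = mc_p, expected = ct$expected)
}

#' Wright's fixation index for two populations
#'
#' The simple Wright/Nei two-population form: Fst = (Ht - Hs) / Ht, where Ht
#' is the expected heterozygosity 2*pbar*qbar at the sample-size-weighted mean
#' allele frequency and Hs the weighted mean of the within-group
#' heterozygosities 2pq. No small-sample bias correction is applied: the
#' index is used here as a coarse screening filter, not an estimator of a
#' demographic parameter. Returns 0 when the pooled locus is monomorphic.
#' Sampling noise can make the raw index negative; it is floored at 0 for
#' screening, and [wright_fst()] itself returns the floored value with the
#' raw value as an attribute.
#'
#' @param p1,p2 Reference-allele frequency in each group.
#' @param n1,n2 Number of typed diploid individuals in each group.
#' @return Fst in \[0, 1\]; attribute `"raw"` holds the unfloored value.
#' @export
wright_fst <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 > 0, n2 > 0)
  w <- c(n1, n2) / (n1 + n2)
  pbar <- w[1] * p1 + w[2] * p2
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(structure(0, raw = 0))
  hs <- w[1] * 2 * p1 * (1 - p1) + w[2] * 2 * p2 * (1 - p2)
  raw <- (ht - hs) / ht
  structure(max(0, raw), raw = raw)
}

#' Fst screening rule for candidate SNPs
#'
#' Intronic SNPs pass when Fst > 0.15; non-synonymous SNPs when Fst > 0.05;
#' any other annotation context uses the conservative 0.15 threshold. Both
#' inequalities are strict.
#'
#' @param fst Fixation index (floored at 0).
#' @param context Locus annotation context (see [locus()]).
#' @return Logical: does the locus pass the screen?
#' @export
screen_locus <- function(fst,
                         context = c("utr", "intronic", "non_synonymous",
                                     "other")) {
  context <- match.arg(context)
  threshold <- if (context == "non_synonymous") 0.05 else 0.15
  fst > threshold
}

#' Compare genotype and allele frequencies between fecundity groups
#'
#' For every locus: the 2 x 3 genotype contingency chi-square, the 2 x 2
#' allele chi-square, Wright's Fst between polytocous and monotocous pools,
#' and the screening flag.
#'
#' @param mat A [genotype_matrix()].
#' @param meta Metadata data.frame with `fecundity_group` (see
#'   [read_sample_meta()]); samples without a group are dropped.
#' @return A data.frame, one row per locus, with per-group counts, test
#'   results, `fst` and `passes_screen`.
#' @export
compare_groups <- function(mat, meta) {
  meta <- meta[meta$sample_id %in% mat$samples &
                 meta$fecundity_group %in% c("polytocous", "monotocous"), ]
  poly <- meta$sample_id[meta$fecundity_group == "polytocous"]
  mono <- meta$sample_id[meta$fecundity_group == "monotocous"]
  if (!length(poly) || !length(mono))
    stop("both fecundity groups must be present", call. = FALSE)
  rows <- lapply(mat$loci, function(loc) {
    cp <- count_genotypes(mat, loc$id, poly)
    cm <- count_genotypes(mat, loc$id, mono)
    gt <- rbind(polytocous = c(cp$n_homo_ref, cp$n_het, cp$n_homo_alt),
                monotocous = c(cm$n_homo_ref, cm$n_het, cm$n_homo_alt))
    at <- rbind(polytocous = allele_counts_from_genotypes(cp),
                monotocous = allele_counts_from_genotypes(cm))
    g <- contingency_chi_square(gt)
    a <- contingency_chi_square(at)
    fst <- wright_fst(allele_frequencies(cp)[1L], n_typed(cp),
                      allele_frequencies(cm)[1L], n_typed(cm))
    data.frame(
      gene = loc$gene, locus = loc$id, context = loc$context,
      n_poly = n_typed(cp), n_mono = n_typed(cm),
      poly_homo_ref = cp$n_homo_ref, poly_het = cp$n_het,
      poly_homo_alt = cp$n_homo_alt,
      mono_homo_ref = cm$n_homo_ref, mono_het = cm$n_het,
      mono_homo_alt = cm$n_homo_alt,
      freq_ref_poly = unname(allele_frequencies(cp)[1L]),
      freq_ref_mono = unname(allele_frequencies(cm)[1L]),
      genotype_chi2 = g$chi2, genotype_p = g$p, genotype_mc_p = g$mc_p,
      allele_chi2 = a$chi2, allele_p = a$p, allele_mc_p = a$mc_p,
      fst = as.numeric(fst), fst_raw = attr(fst, "raw"),
      passes_screen = screen_locus(as.numeric(fst), loc$context),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
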