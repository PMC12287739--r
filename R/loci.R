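#' Define a biallelic SNP locus
#'
#' A locus carries its marker label (HGVS-style, e.g. `"c.*127T>C"`), the gene
#' it sits in, its two alleles and an annotation context used by the Fst
#' screening rule.
#'
#' @param id Marker label, unique within a panel.
#' @param gene Gene symbol, e.g. `"LIFR"`.
#' @param allele_ref,allele_alt Single nucleotide characters (A/C/G/T);
#'   `allele_ref` is the first-named allele of the marker label.
#' @param context Annotation context: `"utr"`, `"intronic"`,
#'   `"non_synonymous"` or `"other"`. Drives [screen_locus()] thresholds.
#' @return An object of class `"snp_locus"`.
#' @examples
#' locus("c.*127T>C", "LIFR", "T", "C", context = "utr")
#' @export
locus <- function(id, gene, allele_ref, allele_alt,
                  context = c("utr", "intronic", "non_synonymous", "other")) {
  context <- match.arg(context)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(gene), length(gene) == 1L)
  nts <- c("A", "C", "G", "T")
  if (!(allele_ref %in% nts) || !(allele_alt %in% nts))
    stop("alleles must be single nucleotides A/C/G/T, got '",
         allele_ref, "'/'", allele_alt, "'", call. = FALSE)
  if (allele_ref == allele_alt)
    stop("locus '", id, "' must be biallelic (ref == alt)", call. = FALSE)
  structure(list(id = id, gene = gene, allele_ref = allele_ref,
                 allele_alt = allele_alt, context = context),
            class = "snp_locus")
}

#' @export
print.snp_locus <- function(x, ...) {
  cat(sprintf("<snp_locus> %s %s [%s/%s] (%s)\n",
              x$gene, x$id, x$allele_ref, x$allele_alt, x$context))
  invisible(x)
}

# canonical genotype strings for a locus, in dosage order hom-ref, het, hom-alt
genotype_levels <- function(loc) {
  c(strrep(loc$allele_ref, 2),
    canonical_call(paste0(loc$allele_ref, loc$allele_alt)),
    strrep(loc$allele_alt, 2))
}

#' The six candidate loci genotyped in the sheep breed panels
#'
#' Marker definitions for the SPOCK1 (3' UTR x3), ADAMTS1 (coding,
#' non-synonymous), HBEGF (3' UTR) and LIFR (3' UTR) candidate SNPs.
#'
#' @return A named list of [locus()] objects keyed by marker id.
#' @export
sheep_candidate_loci <- function() {
  defs <- list(
    locus("c.*1633T>C", "SPOCK1",  "T", "C", "utr"),
    locus("c.*1388T>C", "SPOCK1",  "T", "C", "utr"),
    locus("c.*1095G>A", "SPOCK1",  "G", "A", "utr"),
    locus("c.1847A>G",  "ADAMTS1", "A", "G", "non_synonymous"),
    locus("c.*2403T>C", "HBEGF",   "T", "C", "utr"),
    locus("c.*127T>C",  "LIFR",    "T", "C", "utr"))
  stats::setNames(defs, vapply(defs, `[[`, "", "id"))
}
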