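# Small in-code fixtures shared across test files.

tc_locus <- function(id = "c.*127T>C", gene = "LIFR")
  locus(id, gene, "T", "C", "utr")

# genotype matrix holding given counts of TT / CT / CC (+ missing) at one
# T/C locus
matrix_from_counts <- function(n_tt, n_ct, n_cc, n_miss = 0,
                               loc = tc_locus()) {
  calls <- c(rep("TT", n_tt), rep("CT", n_ct), rep("CC", n_cc),
             rep(NA, n_miss))
  n <- length(calls)
  genotype_matrix(sprintf("s%04d", seq_len(n)),
                  stats::setNames(list(loc), loc$id),
                  matrix(calls, ncol = 1))
}

# random biallelic genotype matrix over several loci, possibly with missing
random_matrix <- function(n = 20, seed = 1, miss_rate = 0.1) {
  set.seed(seed)
  loci <- list(locus("snpA", "G1", "T", "C", "utr"),
               locus("snpB", "G2", "A", "G", "intronic"),
               locus("snpC", "G3", "C", "G", "non_synonymous"))
  calls <- sapply(loci, function(loc) {
    g <- sample(genotype_levels(loc), n, replace = TRUE)
    g[runif(n) < miss_rate] <- NA
    g
  })
  genotype_matrix(sprintf("s%03d", seq_len(n)), loci, calls)
}

han_frequencies <- function() lambsnp:::panel_frequencies()[, "Small-tailed Han"]

# one simulated validation cohort: genotypes + calibrated phenotypes
simulate_cohort <- function(seed, n = 384) {
  loci <- sheep_candidate_loci()
  sc <- breed_scenario("Han", n, "polytocous", p = han_frequencies(),
                       seed = seed)
  mat <- simulate_genotypes(sc, loci)
  phen <- simulate_phenotypes(mat, default_phenotype_scenario(seed = seed + 1L))
  list(mat = mat, phen = phen)
}

letters_disjoint <- function(a, b) {
  !any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
}
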