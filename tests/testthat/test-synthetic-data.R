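test_that("genotype sampling follows the inbreeding-adjusted HWE model", {
  loci <- list("L" = locus("L", "G", "T", "C", "utr"))
  big <- simulate_genotypes(
    breed_scenario("b", 10000, "polytocous", p = c(L = 0.5), seed = 4), loci)
  cts <- count_genotypes(big, "L")
  n <- n_typed(cts)
  expect_equal(cts$n_homo_ref / n, 0.25, tolerance = 0.02)
  expect_equal(cts$n_het / n, 0.5, tolerance = 0.02)
  # empirical allele frequency converges to the scenario p
  expect_equal(unname(allele_frequencies(cts)[1]), 0.5,
               tolerance = 3 * sqrt(0.25 / (2 * 10000)))

  inbred <- simulate_genotypes(
    breed_scenario("b", 500, "polytocous", p = c(L = 0.3), f = 1, seed = 4),
    loci)
  expect_equal(count_genotypes(inbred, "L")$n_het, 0)

  expect_error(
    breed_scenario("b", 10, "polytocous", p = c(L = 0.9), f = -0.5),
    "infeasible")
})

test_that("simulation is deterministic under a fixed seed", {
  loci <- sheep_candidate_loci()
  sc <- breed_scenario("Han", 50, "polytocous", p = han_frequencies(),
                       seed = 99)
  m1 <- simulate_genotypes(sc, loci)
  m2 <- simulate_genotypes(sc, loci)
  expect_identical(m1$calls, m2$calls)
  ph1 <- simulate_phenotypes(m1, default_phenotype_scenario(seed = 5))
  ph2 <- simulate_phenotypes(m1, default_phenotype_scenario(seed = 5))
  expect_identical(ph1, ph2)
  m3 <- simulate_genotypes(
    breed_scenario("Han", 50, "polytocous", p = han_frequencies(),
                   seed = 100), loci)
  expect_false(identical(m1$calls, m3$calls))
})

test_that("noiseless phenotypes reproduce the baselines exactly", {
  loci <- sheep_candidate_loci()
  mat <- simulate_genotypes(
    breed_scenario("Han", 20, "polytocous", p = han_frequencies(), seed = 1),
    loci)
  ph <- simulate_phenotypes(mat, phenotype_scenario(
    baselines = c(2, 2, 2), sd = 0, miss3 = 0, seed = 1))
  expect_true(all(ph$parity1 == 2 & ph$parity2 == 2 & ph$parity3 == 2))
  expect_true(all(ph$average == 2))
  # lamb counts always integers in [0, 6]
  wild <- simulate_phenotypes(mat, phenotype_scenario(
    baselines = c(8, -3, 2), sd = 2, miss3 = 0, seed = 2))
  for (p in c("parity1", "parity2", "parity3")) {
    expect_true(all(wild[[p]] >= 0 & wild[[p]] <= 6))
    expect_true(all(wild[[p]] == round(wild[[p]])))
  }
})

test_that("HWE test calibration: nominal size at f = 0, power under f > 0", {
  loci <- list("L" = locus("L", "G", "T", "C", "utr"))
  rej0 <- 0
  rej3 <- 0
  n_rep <- 300
  for (r in seq_len(n_rep)) {
    m0 <- simulate_genotypes(
      breed_scenario("b", 96, "polytocous", p = c(L = 0.5), seed = r), loci)
    if (hwe_chi_square(count_genotypes(m0, "L"))$p < 0.05) rej0 <- rej0 + 1
    m3 <- simulate_genotypes(
      breed_scenario("b", 96, "polytocous", p = c(L = 0.5), f = 0.3,
                     seed = 10000 + r), loci)
    if (hwe_chi_square(count_genotypes(m3, "L"))$p < 0.05) rej3 <- rej3 + 1
  }
  # nominal 5% within 3 binomial standard errors at 300 replicates
  slack <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rej0 / n_rep, 0.05 - slack)
  expect_lte(rej0 / n_rep, 0.05 + slack)
  expect_gt(rej3 / n_rep, 0.5)
})

test_that("the five-breed panel matches the study design", {
  panel <- make_paper_panel(seed = 2)
  expect_equal(length(panel$genotypes$samples), 768)
  expect_equal(unname(table(panel$meta$breed)[
    c("Small-tailed Han", "Cele black", "Hu", "Sunite", "Bamei mutton")]),
    c(384L, 96L, 96L, 96L, 96L), ignore_attr = TRUE)
  expect_equal(sum(panel$meta$fecundity_group == "polytocous"), 576)

  # monotocous Bamei panel: allele frequency near its observed 0.31 and
  # genotype classes near the random-mating expectations (3 SE slack)
  bam <- panel$meta$sample_id[panel$meta$breed == "Bamei mutton"]
  cts <- count_genotypes(panel$genotypes, "c.*127T>C", bam)
  n <- n_typed(cts)
  pt <- 0.31
  expect_lt(abs(allele_frequencies(cts)[["p_ref"]] - pt),
            3 * sqrt(pt * (1 - pt) / (2 * n)))
  hw <- c(pt^2, 2 * pt * (1 - pt), (1 - pt)^2)
  obs <- c(cts$n_homo_ref, cts$n_het, cts$n_homo_alt) / n
  expect_true(all(abs(obs - hw) < 3 * sqrt(hw * (1 - hw) / n)))

  # validation-cohort LIFR PIC lands near its published value
  han <- panel$meta$sample_id[panel$meta$breed == "Small-tailed Han"]
  p <- allele_frequencies(count_genotypes(panel$genotypes, "c.*127T>C", han))
  expect_equal(pic(p), 0.31, tolerance = 0.03)

  # phenotypes only for the validation cohort, with some parity-3 gaps
  expect_true(all(panel$phenotypes$sample_id %in% han))
  expect_equal(nrow(panel$phenotypes), 384)
})
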