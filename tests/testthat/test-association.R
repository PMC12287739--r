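test_that("with one balanced factor, least-squares means equal raw means", {
  loc <- tc_locus()
  calls <- rep(c("TT", "CT", "CC"), each = 6)
  mat <- genotype_matrix(sprintf("s%02d", 1:18),
                         stats::setNames(list(loc), loc$id),
                         matrix(calls, ncol = 1))
  set.seed(2)
  y <- round(pmax(0, rnorm(18, rep(c(2, 1.8, 1), each = 6), 0.5)))
  phen <- data.frame(sample_id = mat$samples, parity1 = y, parity2 = y,
                     parity3 = y, average = y)
  res <- fit_lsm(phen, mat, response = "average")
  raw <- tapply(y, factor(calls, levels = c("TT", "CT", "CC")), mean)
  expect_equal(stats::setNames(res$lsm, res$level), raw[res$level],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$n, rep(6L, 3))
  expect_true(all(res$se > 0))
})

test_that("compact letter display is consistent with its p-value matrix", {
  set.seed(13)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    lev <- paste0("g", seq_len(k))
    means <- stats::setNames(sort(runif(k, 0, 3), decreasing = TRUE), lev)
    pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      pmat[a, b] <- pmat[b, a] <- runif(1)
    lets <- compact_letter_display(means, pmat, alpha = 0.3)
    expect_true(all(nzchar(lets)))
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      share <- !letters_disjoint(lets[a], lets[b])
      if (pmat[a, b] < 0.3) {
        expect_false(share)   # significant pairs never share a letter
      } else {
        expect_true(share)    # non-significant pairs always share one
      }
    }
  }
  # the highest mean carries "a"
  means <- c(hi = 2, mid = 1.5, lo = 1)
  pmat <- matrix(0.01, 3, 3, dimnames = list(names(means), names(means)))
  diag(pmat) <- NA
  expect_identical(unname(compact_letter_display(means, pmat)[1]), "a")
})

test_that("calibrated simulations recover the genotype effects and letters", {
  ok <- 0
  maes <- numeric(0)
  target <- c(TT = 1.55, CT = 1.48, CC = 1.00)
  for (r in 1:10) {
    cohort <- simulate_cohort(seed = 400 + 10 * r)
    res <- fit_lsm(cohort$phen, cohort$mat, response = "average",
                   loci = "c.*127T>C")
    lsm <- stats::setNames(res$lsm, res$level)
    let <- stats::setNames(res$letter, res$level)
    maes <- c(maes, mean(abs(lsm[names(target)] - target)))
    if (names(which.min(lsm)) == "CC" &&
        letters_disjoint(let[["CC"]], let[["TT"]]) &&
        letters_disjoint(let[["CC"]], let[["CT"]]))
      ok <- ok + 1
  }
  expect_gte(ok, 9)
  expect_lt(mean(maes), 0.1)
})

test_that("breaking the genotype-phenotype link removes letter separation", {
  cohort <- simulate_cohort(seed = 77)
  same <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(3000 + r)
    p2 <- cohort$phen
    p2$sample_id <- sample(p2$sample_id)
    res <- fit_lsm(p2, cohort$mat, response = "average", loci = "c.*127T>C")
    if (length(unique(res$letter)) == 1) same <- same + 1
  }
  # under the null, P(any of the 3 unadjusted pairwise tests rejects) <= 3 * 0.05
  # (Bonferroni), so all-identical letters in >= 85% of replicates up to
  # Monte Carlo noise
  expect_gte(same / n_rep, 1 - 3 * 0.05 - 3 * sqrt(0.15 * 0.85 / n_rep))
})

test_that("interaction screen controls its error rate and finds real cells", {
  null_ps <- numeric(0)
  found <- 0
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    loci <- sheep_candidate_loci()
    mat <- simulate_genotypes(
      breed_scenario("Han", 384, "polytocous", p = han_frequencies(),
                     seed = 5000 + r), loci)
    ph_add <- simulate_phenotypes(mat, default_phenotype_scenario(
      seed = 6000 + r))
    isc <- interaction_screen(ph_add, mat, response = "average")
    expect_equal(nrow(isc), 6)     # 4 gene factors -> 6 pairs
    null_ps <- c(null_ps, isc$p)
    sc_int <- phenotype_scenario(
      effects = list("c.*127T>C" = c(TT = 0.067, CT = -0.003, CC = -0.483)),
      interactions = data.frame(locus1 = "c.*127T>C", locus2 = "c.*2403T>C",
                                effect = 0.8),
      seed = 7000 + r)
    ph_int <- simulate_phenotypes(mat, sc_int)
    isc2 <- interaction_screen(ph_int, mat, response = "average")
    hit <- isc2$significant[isc2$locus1 %in% c("c.*127T>C", "c.*2403T>C") &
                              isc2$locus2 %in% c("c.*127T>C", "c.*2403T>C")]
    if (hit) found <- found + 1
  }
  # per-pair type-I rate close to alpha (90 tests; binomial slack)
  expect_lt(mean(null_ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(null_ps)))
  expect_gt(found / n_rep, 0.8)    # 0.8-lamb double-het cell is detectable
})

test_that("a constant response yields zero F statistics", {
  cohort <- simulate_cohort(seed = 21)
  ph <- cohort$phen
  ph$average <- 2
  isc <- interaction_screen(ph, cohort$mat, response = "average")
  expect_equal(isc$F, rep(0, 6))
  expect_false(any(isc$significant))
})

test_that("fewer than two genotype levels yields means without contrasts", {
  loc <- tc_locus()
  mat <- genotype_matrix(sprintf("s%d", 1:6),
                         stats::setNames(list(loc), loc$id),
                         matrix(rep("TT", 6), ncol = 1))
  phen <- data.frame(sample_id = mat$samples, parity1 = c(2, 1, 2, 3, 2, 1),
                     parity2 = 1, parity3 = 1, average = c(2, 1, 2, 3, 2, 1))
  res <- fit_lsm(phen, mat, response = "average")
  expect_equal(nrow(res), 1)
  expect_equal(res$lsm, mean(phen$average))
  expect_true(is.na(res$letter))
})

test_that("the pooled parity-adjusted fit preserves the genotype ranking", {
  cohort <- simulate_cohort(seed = 55)
  pooled <- fit_lsm_pooled(cohort$phen, cohort$mat, focal = "c.*127T>C")
  expect_equal(nrow(pooled), 3)
  lsm <- stats::setNames(pooled$lsm, pooled$level)
  expect_equal(names(which.min(lsm)), "CC")
})

test_that("rendered genotype tables follow the publication conventions", {
  res <- data.frame(
    locus = "c.*127T>C", gene = "LIFR", response = "average",
    level = c("TT", "CT", "CC"), n = c(208L, 148L, 28L),
    lsm = c(1.55, 1.48, 1.00), se = c(0.066, 0.077, 0.106),
    letter = c("a", "a", "b"), stringsAsFactors = FALSE)
  tab <- render_table6(res)
  expect_identical(tab$average[1], "1.55 ± 0.066^a^")
  expect_identical(tab$genotype[1], "TT (208)")

  # all-same letters are dropped from the display
  res$letter <- "a"
  tab2 <- render_table6(res)
  expect_identical(tab2$average[3], "1.00 ± 0.106")

  # empty cells render as an em dash
  res$lsm[3] <- NA
  expect_identical(render_table6(res)$average[3], "—")
})
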