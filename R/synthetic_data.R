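#' Describe one breed panel for simulation
#'
#' Genotypes are drawn per individual from the inbreeding-adjusted
#' Hardy-Weinberg probabilities `(p^2 + Fpq, 2pq(1-F), q^2 + Fpq)`. `f = 0`
#' is random mating; `f > 0` produces the heterozygote deficit of a
#' population departing from equilibrium (the mechanism used to emulate the
#' one breed x locus combination observed out of equilibrium); `f = 1` is
#' full inbreeding.
#'
#' @param breed Breed name.
#' @param n Number of ewes in the panel.
#' @param fecundity_group `"polytocous"` or `"monotocous"`.
#' @param p Named vector of reference-allele frequencies, one per locus id.
#' @param f Named vector of inbreeding coefficients (recycled scalar allowed;
#'   default 0). Must keep all three genotype probabilities non-negative.
#' @param seed Integer seed; all randomness in the panel flows from it.
#' @return An object of class `"breed_scenario"`.
#' @export
breed_scenario <- function(breed, n,
                           fecundity_group = c("polytocous", "monotocous"),
                           p, f = 0, seed = 1L) {
  fecundity_group <- match.arg(fecundity_group)
  stopifnot(n >= 1, all(p >= 0), all(p <= 1), !is.null(names(p)))
  if (length(f) == 1L) f <- stats::setNames(rep(f, length(p)), names(p))
  stopifnot(identical(sort(names(f)), sort(names(p))))
  for (id in names(p)) {
    pr <- geno_probs(p[[id]], f[[id]])
    if (any(pr < 0))
      stop("inbreeding coefficient f = ", f[[id]], " is infeasible for p = ",
           p[[id]], " at locus ", id, call. = FALSE)
  }
  structure(list(breed = breed, n = as.integer(n),
                 fecundity_group = fecundity_group, p = p, f = f,
                 seed = as.integer(seed)),
            class = "breed_scenario")
}

geno_probs <- function(p, f) {
  q <- 1 - p
  c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
}

#' Simulate genotypes for a breed panel
#'
#' @param scenario A [breed_scenario()].
#' @param loci Named list of [locus()] definitions covering `names(scenario$p)`.
#' @param id_prefix Prefix for generated sample ids.
#' @return A [genotype_matrix()]; deterministic given `scenario$seed`.
#' @export
simulate_genotypes <- function(scenario, loci, id_prefix = scenario$breed) {
  stopifnot(all(names(scenario$p) %in% names(loci)))
  loci <- loci[names(scenario$p)]
  samples <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]+", "_", id_prefix),
                     seq_len(scenario$n))
  calls <- with_local_seed(scenario$seed, {
    m <- matrix(NA_character_, scenario$n, length(loci))
    for (j in seq_along(loci)) {
      lv <- genotype_levels(loci[[j]])
      pr <- geno_probs(scenario$p[[j]], scenario$f[[j]])
      m[, j] <- sample(lv, scenario$n, replace = TRUE, prob = pr)
    }
    m
  })
  genotype_matrix(samples, loci, calls)
}

#' Describe the litter-size phenotype generator
#'
#' Per ewe and parity, the latent lambing number is
#' `baseline[parity] + sum of per-locus genotype effects (+ interactions) +
#' Normal(0, sd)` noise; the recorded value is rounded to an integer and
#' clipped to \[0, 6\], since real lambing records are small integers. A
#' fraction of third-parity records is set missing (ewes not yet at third
#' lambing).
#'
#' @param effects Named list: locus id -> named numeric vector of additive
#'   effects per genotype level (lambs). Levels absent from the vector get 0.
#' @param baselines Length-3 numeric: latent mean lambing number at parities
#'   1-3 for an ewe with all effects zero.
#' @param sd Residual standard deviation (lambs).
#' @param interactions Optional data.frame with columns `locus1`, `locus2`,
#'   `effect`: the effect (lambs) is added when the ewe is heterozygous at
#'   both loci, a simple non-additive cell used for power checks.
#' @param miss3 Probability that parity 3 is missing.
#' @param seed Integer seed.
#' @return An object of class `"phenotype_scenario"`.
#' @export
phenotype_scenario <- function(effects = list(),
                               baselines = c(2.0, 1.7, 0.75),
                               sd = 0.7, interactions = NULL,
                               miss3 = 0.05, seed = 1L) {
  stopifnot(length(baselines) == 3, sd >= 0, miss3 >= 0, miss3 <= 1)
  structure(list(effects = effects, baselines = baselines, sd = sd,
                 interactions = interactions, miss3 = miss3,
                 seed = as.integer(seed)),
            class = "phenotype_scenario")
}

#' Simulate per-parity lambing numbers for genotyped ewes
#'
#' @param mat A [genotype_matrix()] (one row per ewe).
#' @param scenario A [phenotype_scenario()]; effects must refer to loci
#'   present in `mat`.
#' @return A phenotype data.frame (`sample_id`, `parity1..3`, `average`),
#'   deterministic given `scenario$seed`.
#' @export
simulate_phenotypes <- function(mat, scenario) {
  n <- length(mat$samples)
  eff <- numeric(n)
  for (id in names(scenario$effects)) {
    if (!id %in% names(mat$loci))
      stop("effect refers to unknown locus '", id, "'", call. = FALSE)
    ev <- scenario$effects[[id]]
    add <- ev[mat$calls[, id]]
    add[is.na(add)] <- 0
    eff <- eff + add
  }
  if (!is.null(scenario$interactions)) {
    for (r in seq_len(nrow(scenario$interactions))) {
      l1 <- scenario$interactions$locus1[r]
      l2 <- scenario$interactions$locus2[r]
      het1 <- mat$calls[, l1] == genotype_levels(mat$loci[[l1]])[2L]
      het2 <- mat$calls[, l2] == genotype_levels(mat$loci[[l2]])[2L]
      both <- !is.na(het1) & !is.na(het2) & het1 & het2
      eff <- eff + ifelse(both, scenario$interactions$effect[r], 0)
    }
  }
  out <- with_local_seed(scenario$seed, {
    df <- data.frame(sample_id = mat$samples, stringsAsFactors = FALSE)
    for (k in 1:3) {
      y <- scenario$baselines[k] + eff + stats::rnorm(n, 0, scenario$sd)
      df[[paste0("parity", k)]] <- pmin(6, pmax(0, round(y)))
    }
    drop3 <- stats::runif(n) < scenario$miss3
    df$parity3[drop3] <- NA_real_
    df
  })
  out$average <- rowMeans(out[c("parity1", "parity2", "parity3")],
                          na.rm = TRUE)
  out
}

# derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 100 + k) %% 2147483647)

# Reference-allele frequencies of the six candidate loci in the five breed
# panels (rows: loci; columns: breeds), as observed in the genotyped panels.
panel_frequencies <- function() {
  breeds <- c("Small-tailed Han", "Cele black", "Hu", "Sunite", "Bamei mutton")
  m <- rbind(
    "c.*1633T>C" = c(0.85, 0.72, 0.81, 0.80, 0.84),
    "c.*1388T>C" = c(0.85, 0.72, 0.81, 0.80, 0.84),
    "c.*1095G>A" = c(0.66, 0.47, 0.39, 0.66, 0.83),
    "c.1847A>G"  = c(0.92, 0.98, 0.97, 0.88, 1.00),
    "c.*2403T>C" = c(0.93, 0.74, 0.96, 0.87, 0.89),
    "c.*127T>C"  = c(0.74, 0.78, 0.59, 0.70, 0.31))
  colnames(m) <- breeds
  m
}

#' Default litter-size scenario calibrated to the observed genotype means
#'
#' LIFR c.*127T>C genotype effects are set so the latent average-parity means
#' are 1.55 (TT), 1.48 (CT) and 1.00 (CC) lambs around parity baselines
#' (2.0, 1.7, 0.75); the other loci carry no effect, matching their
#' non-significant associations. Residual sd 0.7 lambs.
#'
#' @param seed Integer seed.
#' @return A [phenotype_scenario()].
#' @export
default_phenotype_scenario <- function(seed = 1L) {
  phenotype_scenario(
    effects = list("c.*127T>C" = c(TT = 0.067, CT = -0.003, CC = -0.483)),
    baselines = c(2.0, 1.7, 0.75), sd = 0.7, miss3 = 0.05, seed = seed)
}

#' Build the full five-breed study panel
#'
#' Simulates the five breed panels (384 + 96 + 96 + 96 + 96 ewes; three
#' polytocous, two monotocous breeds) at the observed allele frequencies of
#' the six candidate loci, with an inbreeding coefficient of 0.28 at LIFR
#' c.*127T>C in the Sunite panel (the one breed x locus combination observed
#' out of Hardy-Weinberg equilibrium) and random mating elsewhere.
#' Litter-size phenotypes are generated for the small-tailed Han validation
#' cohort only, via [default_phenotype_scenario()].
#'
#' @param seed Integer master seed; per-breed and phenotype seeds are derived
#'   from it.
#' @return List with `genotypes` (a [genotype_matrix()]), `meta` (sample
#'   metadata data.frame) and `phenotypes` (phenotype data.frame for the
#'   small-tailed Han ewes).
#' @export
make_paper_panel <- function(seed = 1L) {
  loci <- sheep_candidate_loci()
  freqs <- panel_frequencies()
  sizes <- c("Small-tailed Han" = 384L, "Cele black" = 96L, "Hu" = 96L,
             "Sunite" = 96L, "Bamei mutton" = 96L)
  groups <- c("Small-tailed Han" = "polytocous", "Cele black" = "polytocous",
              "Hu" = "polytocous", "Sunite" = "monotocous",
              "Bamei mutton" = "monotocous")
  mats <- list()
  metas <- list()
  for (i in seq_along(sizes)) {
    b <- names(sizes)[i]
    f <- stats::setNames(rep(0, nrow(freqs)), rownames(freqs))
    if (b == "Sunite") f[["c.*127T>C"]] <- 0.28
    sc <- breed_scenario(b, sizes[[b]], groups[[b]],
                         p = freqs[, b], f = f, seed = derive_seed(seed, i))
    mats[[b]] <- simulate_genotypes(sc, loci)
    metas[[b]] <- data.frame(sample_id = mats[[b]]$samples, breed = b,
                             fecundity_group = groups[[b]],
                             stringsAsFactors = FALSE)
  }
  all_calls <- do.call(rbind, lapply(mats, `[[`, "calls"))
  all_samples <- unlist(lapply(mats, `[[`, "samples"), use.names = FALSE)
  genotypes <- genotype_matrix(all_samples, loci, all_calls)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  han <- mats[["Small-tailed Han"]]
  phen <- simulate_phenotypes(han, default_phenotype_scenario(
    seed = derive_seed(seed, 51L)))
  list(genotypes = genotypes, meta = meta, phenotypes = phen)
}
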