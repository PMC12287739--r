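# One genotype factor per gene enters the model. When a gene carries several
# markers the most diverse one (highest observed He) represents it, so the
# design stays full rank; the focal marker always represents its own gene.
representative_loci <- function(mat, focal_id = NULL) {
  ids <- names(mat$loci)
  he <- vapply(ids, function(id) {
    cts <- count_genotypes(mat, id)
    if (n_typed(cts) < 1) return(0)
    expected_heterozygosity(allele_frequencies(cts))
  }, numeric(1))
  genes <- vapply(mat$loci, `[[`, "", "gene")
  reps <- tapply(seq_along(ids), genes, function(idx) ids[idx[which.max(he[idx])]])
  reps <- unname(reps[unique(genes)])
  if (!is.null(focal_id)) {
    focal_gene <- mat$loci[[focal_id]]$gene
    reps[match(focal_gene, unique(genes))] <- focal_id
  }
  reps
}

# complete-case model frame: response plus one droplevels'd factor per model
# locus, columns named by gene symbol
assoc_frame <- function(phen, mat, response, model_loci) {
  idx <- match(phen$sample_id, mat$samples)
  keep <- !is.na(idx)
  phen <- phen[keep, ]
  idx <- idx[keep]
  df <- data.frame(y = phen[[response]])
  for (id in model_loci) {
    loc <- mat$loci[[id]]
    df[[loc$gene]] <- factor(mat$calls[idx, id],
                             levels = genotype_levels(loc))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (v in setdiff(names(df), "y")) df[[v]] <- droplevels(df[[v]])
  df
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start with one group holding every level;
#' each significant pair splits every group containing both; groups contained
#' in another are absorbed. Letters are assigned in order of descending mean,
#' so the highest mean carries "a". Levels sharing a letter do not differ at
#' `alpha`; levels sharing none do.
#'
#' @param means Named numeric vector of group means.
#' @param pmat Symmetric matrix of pairwise p-values (dimnames =
#'   `names(means)`).
#' @param alpha Significance level.
#' @return Named character vector of letter strings.
#' @export
compact_letter_display <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  lev <- names(means)
  stopifnot(!is.null(lev), all(lev %in% rownames(pmat)))
  sets <- list(lev)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pij <- pmat[lev[i], lev[j]]
    if (!is.na(pij) && pij < alpha) {
      new_sets <- list()
      for (s in sets) {
        if (all(c(lev[i], lev[j]) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, lev[i])),
                        list(setdiff(s, lev[j])))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb proper subsets
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) for (b in seq_along(new_sets))
        if (a != b && keep[a] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b))
          keep[a] <- FALSE
      sets <- unique(new_sets[keep])
    }
  }
  ord <- lev[order(-means)]
  first_pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- stats::setNames(rep("", k), lev)
  for (si in seq_along(sets))
    for (l in sets[[si]])
      out[l] <- paste0(out[l], letters[si])
  out
}

#' Least-squares means of lambing number per genotype
#'
#' Fits, for each focal locus, an ordinary least squares model of the chosen
#' lambing-number response on the focal genotype plus one genotype factor per
#' other candidate gene (fixed effects, complete cases across all model
#' factors). Least-squares means per focal genotype level are the model
#' predictions averaged over the observed margins of the other factors
#' (emmeans, proportional weights); pairwise t-contrasts on the model
#' residual variance give significance letters via
#' [compact_letter_display()].
#'
#' @param phen Phenotype data.frame (see [read_phenotype_table()]).
#' @param mat A [genotype_matrix()].
#' @param response One of `"parity1"`, `"parity2"`, `"parity3"`, `"average"`.
#' @param alpha Significance level for the letter display.
#' @param adjust Multiplicity adjustment for the pairwise contrasts:
#'   `"none"` (default, plain t-tests), `"tukey"` or `"bonferroni"`.
#' @param loci Focal loci to report (default: all in `mat`).
#' @return A data.frame with one row per focal locus x genotype level:
#'   `locus`, `gene`, `response`, `level`, `n`, `lsm`, `se`, `letter`.
#' @export
fit_lsm <- function(phen, mat,
                    response = c("average", "parity1", "parity2", "parity3"),
                    alpha = 0.05,
                    adjust = c("none", "tukey", "bonferroni"),
                    loci = NULL) {
  response <- match.arg(response)
  adjust <- match.arg(adjust)
  if (is.null(loci)) loci <- names(mat$loci)
  out <- list()
  for (focal_id in loci) {
    loc <- mat$loci[[focal_id]]
    model_loci <- representative_loci(mat, focal_id)
    df <- assoc_frame(phen, mat, response, model_loci)
    focal <- loc$gene
    levs <- levels(df[[focal]])
    nlev <- table(df[[focal]])
    if (length(levs) < 2L || nrow(df) < length(levs) + 1L) {
      # nothing to contrast: report raw means without letters
      for (lv in levs)
        out[[length(out) + 1L]] <- data.frame(
          locus = focal_id, gene = focal, response = response, level = lv,
          n = as.integer(nlev[lv]), lsm = mean(df$y[df[[focal]] == lv]),
          se = NA_real_, letter = NA_character_, stringsAsFactors = FALSE)
      next
    }
    covars <- setdiff(names(df), c("y", focal))
    covars <- covars[vapply(covars, function(v) nlevels(df[[v]]) >= 2L,
                            logical(1))]
    fml <- stats::reformulate(c(focal, covars), response = "y")
    m <- stats::lm(fml, data = df)
    emm <- emmeans::emmeans(m, specs = focal, weights = "proportional")
    s <- as.data.frame(emm)
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = adjust))
    pmat <- matrix(NA_real_, length(levs), length(levs),
                   dimnames = list(levs, levs))
    for (r in seq_len(nrow(prs))) {
      pair <- strsplit(prs$contrast[r], " - ")[[1]]
      pair <- gsub("^\\(|\\)$", "", pair)
      pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- prs$p.value[r]
    }
    means <- stats::setNames(s$emmean, as.character(s[[1]]))
    lets <- compact_letter_display(means[levs], pmat, alpha)
    for (lv in levs)
      out[[length(out) + 1L]] <- data.frame(
        locus = focal_id, gene = focal, response = response, level = lv,
        n = as.integer(nlev[lv]), lsm = unname(means[lv]),
        se = s$SE[match(lv, as.character(s[[1]]))],
        letter = unname(lets[lv]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled-parity sensitivity fit with a fixed parity effect
#'
#' Stacks the three parities into long format and fits
#' `y ~ parity + G1 + G2 + G3 + G4` (one genotype factor per gene). This is
#' the sensitivity companion to the per-response fits of [fit_lsm()]: it
#' checks that adjusting for parity as a fixed effect does not change the
#' genotype ranking at the focal locus.
#'
#' @inheritParams fit_lsm
#' @param focal Focal locus id.
#' @return A data.frame of least-squares means per focal genotype level, as
#'   in [fit_lsm()], from the pooled model.
#' @export
fit_lsm_pooled <- function(phen, mat, focal, alpha = 0.05,
                           adjust = c("none", "tukey", "bonferroni")) {
  adjust <- match.arg(adjust)
  long <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(sample_id = phen$sample_id, parity = paste0("parity", k),
               y = phen[[paste0("parity", k)]], stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$y), ]
  model_loci <- representative_loci(mat, focal)
  idx <- match(long$sample_id, mat$samples)
  keep <- !is.na(idx)
  long <- long[keep, ]
  idx <- idx[keep]
  df <- data.frame(y = long$y, parity = factor(long$parity))
  for (id in model_loci) {
    loc <- mat$loci[[id]]
    df[[loc$gene]] <- factor(mat$calls[idx, id],
                             levels = genotype_levels(loc))
  }
  df <- df[stats::complete.cases(df), ]
  for (v in setdiff(names(df), "y")) df[[v]] <- droplevels(df[[v]])
  focal_gene <- mat$loci[[focal]]$gene
  covars <- setdiff(names(df), c("y", focal_gene))
  covars <- covars[vapply(covars, function(v) nlevels(df[[v]]) >= 2L,
                          logical(1))]
  m <- stats::lm(stats::reformulate(c(focal_gene, covars), "y"), data = df)
  emm <- emmeans::emmeans(m, specs = focal_gene, weights = "proportional")
  s <- as.data.frame(emm)
  data.frame(locus = focal, gene = focal_gene, level = as.character(s[[1]]),
             lsm = s$emmean, se = s$SE, stringsAsFactors = FALSE)
}

#' Screen locus pairs for genotype-by-genotype interaction
#'
#' For each pair of the four gene-representative loci, compares the additive
#' fixed-effects model with the model plus that pairwise interaction by an
#' F-test (`anova`). Interaction cells with no observations are simply absent
#' from the estimation; `n_cells_missing` records how many of the full
#' genotype-by-genotype grid were unobserved. A constant response gives F = 0.
#'
#' @inheritParams fit_lsm
#' @return A data.frame with one row per locus pair: `locus1`, `locus2`,
#'   `F`, `df1`, `df2`, `p`, `significant`, `n_cells_missing`.
#' @export
interaction_screen <- function(phen, mat,
                               response = c("average", "parity1", "parity2",
                                            "parity3"),
                               alpha = 0.05) {
  response <- match.arg(response)
  model_loci <- representative_loci(mat)
  df <- assoc_frame(phen, mat, response, model_loci)
  vars <- setdiff(names(df), "y")
  vars <- vars[vapply(vars, function(v) nlevels(df[[v]]) >= 2L, logical(1))]
  base <- stats::lm(stats::reformulate(vars, "y"), data = df)
  const <- stats::var(df$y) == 0
  out <- list()
  for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
    g1 <- vars[i]; g2 <- vars[j]
    miss <- sum(table(df[[g1]], df[[g2]]) == 0)
    if (const) {
      f <- 0; p <- 1; df1 <- NA_real_; df2 <- NA_real_
    } else {
      full <- stats::update(base, stats::as.formula(
        paste(". ~ . +", g1, ":", g2)))
      av <- stats::anova(base, full)
      f <- av$F[2]; p <- av$`Pr(>F)`[2]
      df1 <- av$Df[2]; df2 <- av$Res.Df[2]
      if (is.na(f)) { f <- 0; p <- 1 }   # interaction fully aliased
    }
    out[[length(out) + 1L]] <- data.frame(
      locus1 = model_loci[match(g1, vars)], locus2 = model_loci[match(g2, vars)],
      F = f, df1 = df1, df2 = df2, p = p, significant = p < alpha,
      n_cells_missing = miss, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render least-squares means as a publication-style genotype table
#'
#' One row per locus x genotype level, one column per response, cells
#' formatted `"lsm ± se^letter"` (mean to 2 decimals, SE to 3). Letters
#' are dropped for a locus-response where every level shares the same letter;
#' empty cells are an em dash.
#'
#' @param results Data.frame from [fit_lsm()], possibly row-bound across
#'   responses.
#' @return A data.frame with columns `gene`, `locus`, `genotype` (with n) and
#'   one formatted column per response present.
#' @export
render_table6 <- function(results) {
  responses <- unique(results$response)
  key <- results[!duplicated(results[c("gene", "locus", "level")]),
                 c("gene", "locus", "level", "n")]
  fmt <- function(r) {
    if (is.na(r$lsm)) return("—")
    s <- if (is.na(r$se)) sprintf("%.2f", r$lsm) else
      sprintf("%.2f ± %.3f", r$lsm, r$se)
    if (!is.na(r$letter) && nzchar(r$letter)) paste0(s, "^", r$letter, "^")
    else s
  }
  out <- data.frame(gene = key$gene, locus = key$locus,
                    genotype = sprintf("%s (%d)", key$level, key$n),
                    stringsAsFactors = FALSE)
  for (resp in responses) {
    sub <- results[results$response == resp, ]
    # drop letters where nothing differs within a locus
    for (lc in unique(sub$locus)) {
      sel <- sub$locus == lc
      ltr <- sub$letter[sel]
      if (all(is.na(ltr)) || length(unique(ltr[!is.na(ltr)])) <= 1L)
        sub$letter[sel] <- NA_character_
    }
    cells <- vapply(seq_len(nrow(key)), function(i) {
      r <- sub[sub$locus == key$locus[i] & sub$level == key$level[i], ]
      if (!nrow(r)) "—" else fmt(r[1, ])
    }, character(1))
    out[[resp]] <- cells
  }
  out
}
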