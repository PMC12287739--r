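#' Format p-values for reports
#'
#' Values below the display floor print as `"<floor"` (e.g. `"<0.01"`);
#' internal numbers are never floored.
#'
#' @param p Numeric p-values.
#' @param floor Display floor (default 0.01).
#' @param digits Rounding digits (default 2).
#' @return Character vector.
#' @export
format_p <- function(p, floor = 0.01, digits = 2) {
  out <- formatC(round(p, digits), format = "f", digits = digits)
  out[!is.na(p) & p < floor] <- paste0("<", formatC(floor, format = "f",
                                                    digits = digits))
  out[is.na(p)] <- "—"
  out
}

write_report <- function(df, path) {
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' Per-breed marker polymorphism report
#'
#' The display companion of [locus_summary()]: one row per breed x locus with
#' genotype and allele frequencies, PIC, He, Ne and the Hardy-Weinberg
#' p-value, rounded to `digits` decimals.
#'
#' @param mat A [genotype_matrix()].
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param path Optional TSV output path.
#' @param digits Rounding for display (default 2).
#' @return The report data.frame (invisibly written to `path` if given).
#' @export
report_polymorphism <- function(mat, meta, path = NULL, digits = 2) {
  s <- locus_summary(mat, meta)
  if (!nrow(s)) {
    warning("empty genotype matrix: empty polymorphism report",
            call. = FALSE)
    return(write_report(s, path))
  }
  num <- c("geno_homo_ref", "geno_het", "geno_homo_alt", "freq_ref",
           "freq_alt", "pic", "he", "ne")
  for (v in num) s[[v]] <- round(s[[v]], digits)
  s$hwe_p <- format_p(s$hwe_p, floor = 10^-digits, digits = digits)
  out <- s[c("gene", "locus", "breed", "geno_homo_ref", "geno_het",
             "geno_homo_alt", "freq_ref", "freq_alt", "pic", "he", "ne",
             "hwe_p", "polymorphism")]
  write_report(out, path)
}

#' Fecundity-group comparison report
#'
#' The display companion of [compare_groups()]: one row per locus x group
#' with genotype frequencies (counts), the genotype and allele chi-square
#' p-values (floored for display as `"<0.01"`), allele frequencies, Fst and
#' the screening flag.
#'
#' @inheritParams report_polymorphism
#' @return The report data.frame.
#' @export
report_group_comparison <- function(mat, meta, path = NULL, digits = 2) {
  cg <- compare_groups(mat, meta)
  fmt_geno <- function(freq, count)
    sprintf(paste0("%.", digits, "f (%d)"), freq, count)
  rows <- list()
  for (i in seq_len(nrow(cg))) {
    r <- cg[i, ]
    for (grp in c("polytocous", "monotocous")) {
      pre <- if (grp == "polytocous") "poly" else "mono"
      nt <- r[[paste0("n_", substr(pre, 1, 4))]]
      hr <- r[[paste0(pre, "_homo_ref")]]
      ht <- r[[paste0(pre, "_het")]]
      ha <- r[[paste0(pre, "_homo_alt")]]
      fr <- r[[paste0("freq_ref_", pre)]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = r$gene, locus = r$locus, group = grp,
        homo_ref = fmt_geno(hr / nt, hr), het = fmt_geno(ht / nt, ht),
        homo_alt = fmt_geno(ha / nt, ha),
        genotype_p = format_p(r$genotype_p, 10^-digits, digits),
        freq_ref = round(fr, digits), freq_alt = round(1 - fr, digits),
        allele_p = format_p(r$allele_p, 10^-digits, digits),
        fst = round(r$fst, 3), passes_screen = r$passes_screen,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write_report(out, path)
}

#' Genotype association report (least-squares means table)
#'
#' Runs [fit_lsm()] for each requested response and renders the
#' publication-style table via [render_table6()].
#'
#' @inheritParams fit_lsm
#' @param responses Responses to include, in column order.
#' @param path Optional TSV output path.
#' @return The rendered report data.frame.
#' @export
report_association <- function(phen, mat,
                               responses = c("parity1", "parity2", "parity3",
                                             "average"),
                               alpha = 0.05,
                               adjust = c("none", "tukey", "bonferroni"),
                               path = NULL) {
  adjust <- match.arg(adjust)
  res <- do.call(rbind, lapply(responses, function(r)
    fit_lsm(phen, mat, response = r, alpha = alpha, adjust = adjust)))
  write_report(render_table6(res), path)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Recognised keys: `genotypes`, `metadata`, `phenotypes`, `outdir`, `alpha`,
#' `p_floor`, `digits`, `adjust`, `seed`.
#'
#' @param path Config file path.
#' @return Named list with defaults filled in (`alpha` 0.05, `p_floor` 0.01,
#'   `digits` 2, `adjust` `"none"`, `seed` 1).
#' @export
read_run_config <- function(path) {
  defaults <- list(alpha = 0.05, p_floor = 0.01, digits = 2,
                   adjust = "none", seed = 1L)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key %in% c("alpha", "p_floor")) val <- as.numeric(val)
      if (key %in% c("digits", "seed")) val <- as.integer(val)
      cfg[[key]] <- val
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)",
                                             call. = FALSE)
  if (cfg$digits < 2) stop("rounding digits must be >= 2", call. = FALSE)
  cfg
}
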