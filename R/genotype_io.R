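# Accepted spellings of a missing genotype call on input; all normalise to NA.
MISSING_MARKERS <- c("", "--", "NN", "./.", ".", "NA")

# "TC" and "CT" are the same unordered diploid call; store alleles sorted
# alphabetically so every heterozygote has one canonical spelling.
canonical_call <- function(x) {
  vapply(x, function(g) {
    if (is.na(g)) return(NA_character_)
    paste(sort(strsplit(g, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a genotype matrix
#'
#' The central container: unordered diploid calls for each sample at each
#' locus. Heterozygotes are canonicalised (alleles sorted alphabetically) and
#' missing calls are `NA`. Calls are validated against each locus' allele
#' pair.
#'
#' @param samples Character vector of sample ids (unique).
#' @param loci Named list of [locus()] objects.
#' @param calls Character matrix, `length(samples)` x `length(loci)`, each
#'   cell a two-character genotype or `NA`.
#' @return An object of class `"genotype_matrix"` with elements `samples`,
#'   `loci` and `calls` (rownames = samples, colnames = locus ids).
#' @export
genotype_matrix <- function(samples, loci, calls) {
  stopifnot(is.character(samples), !anyDuplicated(samples),
            is.list(loci), is.matrix(calls))
  ids <- unname(vapply(loci, `[[`, "", "id"))
  if (anyDuplicated(ids))
    stop("duplicate locus ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  names(loci) <- ids
  if (nrow(calls) != length(samples) || ncol(calls) != length(loci))
    stop("calls grid is ", nrow(calls), "x", ncol(calls),
         " but samples x loci is ", length(samples), "x", length(loci),
         call. = FALSE)
  calls <- matrix(canonical_call(calls), nrow = nrow(calls),
                  ncol = ncol(calls), dimnames = list(samples, ids))
  for (j in seq_along(loci)) {
    valid <- genotype_levels(loci[[j]])
    bad <- !is.na(calls[, j]) & !(calls[, j] %in% valid)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("invalid call '", calls[i, j], "' for sample '", samples[i],
           "' at locus '", ids[j], "' (alleles ", loci[[j]]$allele_ref, "/",
           loci[[j]]$allele_alt, ")", call. = FALSE)
    }
  }
  structure(list(samples = samples, loci = loci, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci (%.1f%% missing)\n",
              length(x$samples), length(x$loci),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read a delimited genotype table
#'
#' Expects a header row with `sample_id` followed by locus ids, one column per
#' locus, cells holding two-character genotypes (`"TT"`, `"TC"`, ...). The
#' empty string, `"--"`, `"NN"`, `"."`, `"NA"` and `"./."` are read as missing.
#' Heterozygotes are canonicalised on input. Cells that cannot be parsed as a
#' two-allele call become missing with one summary warning; a call using a
#' nucleotide the locus does not carry is a hard error naming the sample,
#' locus and raw cell.
#'
#' @param path Path to a TSV (or `.csv`) file.
#' @param loci Named list of [locus()] definitions; the header's locus columns
#'   must all be defined here (extra definitions are ignored).
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, loci) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "")
  if (ncol(raw) < 2L) stop("genotype table needs sample id + >=1 locus column",
                           call. = FALSE)
  ids <- vapply(loci, `[[`, "", "id")
  names(loci) <- ids
  locus_cols <- colnames(raw)[-1L]
  unknown <- setdiff(locus_cols, ids)
  if (length(unknown))
    stop("locus columns without a definition: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  samples <- raw[[1L]]
  calls <- as.matrix(raw[, -1L, drop = FALSE])
  calls[calls %in% MISSING_MARKERS] <- NA_character_
  n_unparseable <- 0L
  for (j in seq_along(locus_cols)) {
    loc <- loci[[locus_cols[j]]]
    cells <- calls[, j]
    ok <- is.na(cells) | grepl("^[ACGT]{2}$", cells)
    # a well-formed nucleotide pair with a foreign allele is a typing-table
    # error, not noise: fail loudly
    formed <- !is.na(cells) & grepl("^[ACGT]{2}$", cells)
    alleles <- c(loc$allele_ref, loc$allele_alt)
    if (any(formed)) {
      chars <- strsplit(cells[formed], "")
      foreign <- vapply(chars, function(a) !all(a %in% alleles), logical(1))
      if (any(foreign)) {
        i <- which(formed)[which(foreign)[1L]]
        stop("unknown allele in cell '", cells[i], "' for sample '",
             samples[i], "' at locus '", loc$id, "'", call. = FALSE)
      }
    }
    n_unparseable <- n_unparseable + sum(!ok)
    cells[!ok] <- NA_character_
    calls[, j] <- cells
  }
  if (n_unparseable > 0L)
    warning(n_unparseable, " unparseable genotype cell(s) set to missing",
            call. = FALSE)
  genotype_matrix(samples, loci[locus_cols], calls)
}

#' Write a genotype matrix as a delimited table
#'
#' Inverse of [read_genotype_table()]: missing calls are written as `"--"`.
#'
#' @param mat A [genotype_matrix()].
#' @param path Output path; `.csv` selects comma separation, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(mat, path) {
  out <- mat$calls
  out[is.na(out)] <- "--"
  df <- data.frame(sample_id = mat$samples, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (breed and fecundity group)
#'
#' @param path Delimited file with columns `sample_id`, `breed`,
#'   `fecundity_group` (`"polytocous"` or `"monotocous"`).
#' @return A data.frame with those three columns.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "breed", "fecundity_group")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- !df$fecundity_group %in% c("polytocous", "monotocous", NA)
  if (any(bad))
    stop("unknown fecundity_group value(s): ",
         paste(unique(df$fecundity_group[bad]), collapse = ", "),
         call. = FALSE)
  df[need]
}

#' Read per-parity lambing-number phenotypes
#'
#' Expects columns `sample_id`, `parity1`, `parity2`, `parity3` (lamb counts,
#' possibly missing). The per-ewe average is the arithmetic mean over the
#' parities actually recorded; an `average` column on input is recomputed.
#' Lamb counts must be non-negative integers within a plausible range
#' (0 to 6).
#'
#' @param path Delimited phenotype file.
#' @return A data.frame `sample_id`, `parity1..3`, `average`.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", "", "-", "—"))
  pcols <- c("parity1", "parity2", "parity3")
  if (!all(c("sample_id", pcols[1L]) %in% colnames(df)))
    stop("phenotype table needs columns sample_id, parity1[, parity2, parity3]",
         call. = FALSE)
  for (p in pcols) if (!p %in% colnames(df)) df[[p]] <- NA_real_
  for (p in pcols) {
    v <- df[[p]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & (v < 0 | v != round(v) | v > 6)
    if (any(bad))
      stop("lamb counts must be integers in [0, 6]; offending ", p, " value ",
           v[which(bad)[1L]], " for sample ", df$sample_id[which(bad)[1L]],
           call. = FALSE)
    df[[p]] <- v
  }
  df$average <- rowMeans(df[pcols], na.rm = TRUE)
  df$average[is.nan(df$average)] <- NA_real_
  df[c("sample_id", pcols, "average")]
}

#' Export a genotype matrix as a minimal VCF
#'
#' Writes a VCFv4.2 file with one record per locus: CHROM = gene symbol,
#' POS = a synthetic ordinal (no genome coordinates are ingested anywhere in
#' this package), ID = marker label, REF = the locus' first-named allele, and
#' a GT field per sample (`0/0`, `0/1`, `1/1`, missing `./.`).
#'
#' @param mat A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_vcf <- function(mat, path) {
  loci <- mat$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=lambsnp",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", mat$samples), collapse = "\t")), con)
  for (j in seq_along(loci)) {
    loc <- loci[[j]]
    lv <- genotype_levels(loc)
    gt <- c("0/0", "0/1", "1/1")[match(mat$calls[, j], lv)]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(loc$gene, j, loc$id, loc$allele_ref, loc$allele_alt,
                       ".", ".", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
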