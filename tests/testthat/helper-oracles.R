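# Independent oracles: closed forms and explicit expected-count tables,
# kept deliberately separate from the package's code paths.

# biallelic closed forms (the package evaluates the general-n summations)
pic_biallelic_oracle <- function(p) {
  q <- 1 - p
  1 - p^2 - q^2 - 2 * p^2 * q^2
}
he_biallelic_oracle <- function(p) 2 * p * (1 - p)
ne_biallelic_oracle <- function(p) 1 / (p^2 + (1 - p)^2)

# Hardy-Weinberg chi-square by writing out the expected-count table
hwe_oracle <- function(n_rr, n_rh, n_aa) {
  n <- n_rr + n_rh + n_aa
  p <- (2 * n_rr + n_rh) / (2 * n)
  q <- 1 - p
  exp <- c(n * p^2, n * 2 * p * q, n * q^2)
  obs <- c(n_rr, n_rh, n_aa)
  chi2 <- sum(ifelse(exp > 0, (obs - exp)^2 / exp, 0))
  if (p %in% c(0, 1)) chi2 <- 0
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Pearson chi-square on a contingency table from first principles
contingency_oracle <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp)^2 / exp)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE), df = df)
}

# two-population fixation index written out step by step
fst_oracle <- function(p1, n1, p2, n2) {
  w1 <- n1 / (n1 + n2)
  w2 <- n2 / (n1 + n2)
  pbar <- w1 * p1 + w2 * p2
  ht <- 2 * pbar * (1 - pbar)
  hs <- w1 * 2 * p1 * (1 - p1) + w2 * 2 * p2 * (1 - p2)
  if (ht == 0) 0 else (ht - hs) / ht
}
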