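---
title: "Candidate-SNP population genetics and litter-size association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-SNP population genetics and litter-size association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambsnp)
```

## The problem

Litter size in sheep is a lowly heritable, economically central trait.
Marker-assisted selection on a few validated SNPs is a practical alternative
to slow phenotypic selection, but a candidate marker is only useful after
three questions are answered in the target populations: is the marker
polymorphic enough to select on, do its frequencies differ between
high-fecundity (polytocous) and low-fecundity (monotocous) breeds, and do
genotype classes differ in recorded lambing number? `lambsnp` implements
that three-stage analysis for biallelic SNPs genotyped in breed panels, with
a validation cohort (here a 384-ewe polytocous breed) carrying per-parity
lambing records.

## Single-locus statistics

All statistics are computed from typed calls only; missing calls shrink the
per-locus sample size and are never counted as alleles. With allele
frequencies $p_i$ estimated by gene counting,

$$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2, \qquad
H_E = 1 - \sum_i p_i^2, \qquad N_E = 1 / \sum_i p_i^2 .$$

For a biallelic locus these satisfy the identity
$\mathrm{PIC} = H_E - 2p^2q^2$ (asserted in the tests), with maxima
$0.375$, $0.5$ and $2$ at $p = 0.5$. Markers are classed as low
($\mathrm{PIC} < 0.25$), moderate ($0.25 \le \mathrm{PIC} < 0.5$) or high
($\ge 0.5$) polymorphism; the class boundaries are inclusive on the left, so
$\mathrm{PIC} = 0.25$ is moderate.

**Hardy–Weinberg test.** Observed genotype counts are compared with
$n(p^2, 2pq, q^2)$ at the observed allele frequencies by a Pearson
chi-square on 1 degree of freedom (three classes, minus one, minus one
estimated frequency), without Yates continuity correction — the uncorrected
statistic reproduces the published per-breed p-values when the genotype
counts are reconstructed from printed frequencies (e.g. a heterozygote
deficit of 29 observed vs 40 expected in a 96-ewe panel gives
$\chi^2 = 7.33$, $p = 0.0068$, printed as 0.01). Degenerate inputs are
defined rather than erroring: a monomorphic locus returns $\chi^2 = 0$,
$p = 1$ (equilibrium by definition), and zero-expectation cells contribute
nothing.

**Reporting precision.** Internal values are full double precision;
`report_polymorphism()` rounds to 2 decimals, the precision at which such
tables are published. Tests on published values compare rounded numbers;
property tests compare at $10^{-9}$.

## Fecundity-group comparison and Fst screening

Breeds are pooled into polytocous and monotocous groups. For each locus the
2×3 genotype table and the 2×2 allele table are tested with a Pearson
chi-square without continuity correction (`stats::chisq.test`); at the
pooled sample sizes this choice is immaterial, and both tables are reported
because either may be the basis of a printed p-value. Empty genotype
columns are dropped with the degrees of freedom adjusted. When any expected
cell falls below 5, the report adds a Monte Carlo p-value (10,000 simulated
tables under fixed margins, fixed internal seed) next to the asymptotic one,
which stays primary.

Between-group differentiation is summarised by the simple Wright/Nei
two-population fixation index
$F_{st} = (H_T - H_S)/H_T$, where $H_T = 2\bar p \bar q$ at the
sample-size-weighted mean frequency and $H_S$ is the weighted mean
within-group $2pq$. No small-sample (Weir–Cockerham) bias correction is
applied: the index feeds a coarse screening filter, not a demographic
estimate. Sampling noise can push the raw index slightly negative; the
returned value is floored at 0 (the raw value is kept as an attribute).
The screen passes intronic SNPs at $F_{st} > 0.15$ and non-synonymous SNPs
at $F_{st} > 0.05$ (strict inequalities); UTR and other contexts use the
conservative 0.15 threshold, since the published screening rule names only
the first two classes.

## Association model

Lambing number is modelled as a continuous response by ordinary least
squares:

$$y = \mu + G_1 + G_2 + G_3 + G_4 + e,$$

with one fixed genotype factor per candidate gene and complete-case rows
across all four factors. Where a gene carries several markers, the most
diverse one (highest observed $H_E$) represents it — except that the focal
marker always represents its own gene — keeping the design full rank.
Separate models are fitted per response (parity 1, 2, 3, and the per-ewe
average of recorded parities); the parity fixed effect enters only a pooled
long-format sensitivity fit (`fit_lsm_pooled()`), since the primary outputs
are per-parity columns. The per-ewe average is computed before modelling,
over the parities actually recorded.

Least-squares means per focal genotype are model predictions averaged over
the observed margins of the other factors (emmeans, proportional weights),
with delta-method standard errors from the model residual variance.
Pairwise genotype contrasts are plain t-tests at $\alpha = 0.05$,
unadjusted by default because the published tables report only a/b letters
at $p < 0.05$ with no named adjustment; Tukey and Bonferroni are available
as options. Letters come from a compact letter display built by greedy
insert-and-absorb over the pairwise p-value matrix, with letters ordered by
descending mean. Treating a count response as Gaussian is a deliberate
simplification matching the published ANOVA; a log-linear count model is out
of scope.

The interaction screen compares the additive model with the model plus each
of the 6 pairwise genotype×genotype interactions by an F-test. Unobserved
interaction cells are simply absent from estimation (their number is
reported); a fully aliased interaction or a constant response yields
$F = 0$.

Two caveats follow from the unadjusted pairwise testing. Under a true null,
the chance that *some* pairwise test rejects is bounded by $k\alpha$ (three
pairs: ~13% observed), so identical letters across all levels are expected
in roughly 85–87% of null datasets, not 95%+; the tests assert the
Bonferroni-derived bound. Likewise all six interaction tests are jointly
non-significant in only ~74–80% of additive datasets.

## The simulator

The generator exists so that every stage of the pipeline can be exercised,
calibrated and power-checked without animal records.

- **Genotypes.** Per individual, genotype probabilities
  $(p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq)$, where the inbreeding coefficient
  $F$ is the Hardy–Weinberg-departure knob: $F = 0$ is random mating,
  $F > 0$ the heterozygote deficit observed in one monotocous panel
  ($F = 0.28$ reproduces its 29/96 observed vs 40/96 expected
  heterozygotes), $F = 1$ full inbreeding. Infeasible $(p, F)$ pairs
  (negative class probabilities) are rejected at scenario construction.
- **Phenotypes.** Latent lambing number = parity baseline + per-locus
  genotype effects (+ optional double-heterozygote interaction cells for
  power checks) + Normal(0, sd) noise, then rounded to integers and clipped
  to [0, 6], because real lambing records are small integers. Parity-3
  records are missing with probability 0.05 (younger ewes not yet at third
  lambing; published genotype-class sizes sit slightly below the cohort
  size). Defaults: baselines (2.0, 1.7, 0.75) lambs for parities 1–3,
  residual sd 0.7 lambs, LIFR-marker effects (+0.067, −0.003, −0.483) so the
  latent average-parity genotype means are 1.55 / 1.48 / 1.00 lambs — the
  published least-squares means — and zero effects elsewhere, matching the
  non-significant loci.
- **Panel.** `make_paper_panel()` assembles the five-breed design
  (384 + 4×96 ewes; three polytocous, two monotocous breeds) at the observed
  allele frequencies of the six loci, and phenotypes the validation cohort
  only. All randomness flows from one master seed via fixed per-stream
  offsets; no hidden global state (the global RNG is saved and restored).

What the simulator does *not* emulate: linkage between the loci (they sit
on different genes and are treated as independent), pedigree and flock
structure, selection dynamics, and the zero-inflation of real third-parity
records (means are matched, not the full distribution). Passing tests
therefore demonstrate correctness of the estimators under the stated
generating model, not robustness to those real-data features.

## Test problem sizes

The suite checks the published single-locus rows exactly at 2-decimal
rounding; oracle equivalence of PIC/He/Ne and both chi-squares against
brute-force re-derivations at $10^{-9}$ on 1,000 random inputs; HWE type-I
error at $n = 96$, $p = 0.5$ over 1,000 seeded replicates (5% ± 2%); and
parameter recovery over 50 seeded 384-ewe cohorts (CC-lower ordering and
letter separation in ≥ 45/50, mean absolute LSM error < 0.1 lambs). Module
tests use 10–300 replicates for the same properties.

## Known limitations

- Two-allele markers only; multi-allelic loci and haplotype statistics are
  out of scope, as are genome coordinates (the VCF export uses synthetic
  ordinal positions).
- The association model is fixed-effects OLS; random animal/flock effects
  and count-likelihood models are not provided.
- The Fst screen is a filter with published thresholds, not an estimator
  with confidence intervals.
- Published least-squares means cannot be reproduced exactly without the
  original lambing records; the association stage is validated by
  calibrated simulation instead.
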