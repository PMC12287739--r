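Package: lambsnp
Title: Candidate SNP Population Genetics and Litter-Size Association in Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for biallelic candidate SNP markers genotyped
    in sheep breed panels. Computes single-locus population-genetic summaries
    (genotype and allele frequencies, polymorphism information content,
    expected heterozygosity, effective allele number, Hardy-Weinberg
    chi-square tests), contingency tests of genotype and allele frequencies
    between polytocous and monotocous fecundity groups with Wright's Fst
    screening, and fixed-effects least-squares-means association of genotypes
    with per-parity lambing number, including pairwise significance letters
    and a locus-pair interaction screen. A seeded simulator generates breed
    panels and litter-size phenotypes with the statistical structure the
    analysis assumes, so the whole pipeline is testable without animal
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    emmeans,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
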