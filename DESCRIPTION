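Package: pixhap
Title: Parent-Informed X-Chromosome Haplotype Association Tests for
    Case-Parent Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Family-based multi-SNP association analysis of X-chromosome
    haplotypes using genotyped case-parent triads. Exploits the absence of
    phase ambiguity on the X given complete triads to reconstruct the three
    parental haplotypes deterministically, builds pseudo-sibling risk sets
    under parental haplotype exchangeability (PHE), and tests haplotype
    effects with an exact conditional-logistic likelihood-ratio test with
    rare-haplotype pooling. Includes a diagnostic test of the PHE assumption
    with an offspring-sex decomposition, a sliding-window scan with
    Bonferroni correction and Manhattan/QQ outputs, a genotype-dependent
    missingness diagnostic, readers and writers for PED/MAP pedigree files,
    and a triad simulator for type-I-error and power studies under
    Hardy-Weinberg and stratified-population nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
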