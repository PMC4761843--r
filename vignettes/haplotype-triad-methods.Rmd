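---
title: "X-chromosome haplotype analysis of case-parent triads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{X-chromosome haplotype analysis of case-parent triads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixhap)
```

## The problem

In a case-parent triad study an affected child and both biological parents
are genotyped, and association is assessed by comparing what the parents
transmitted with what they could have transmitted. Conditioning on the
parents makes the design immune to population stratification, the classic
confounder of case-control association studies. This package analyzes
multi-SNP *haplotypes* on the X chromosome, where the design has a special
advantage: fathers and sons carry a single X, so a complete triad has **no
phase ambiguity**. A daughter inherits her father's entire X haplotype;
subtracting it from her genotype gives her maternal haplotype, and
subtracting that from the mother's genotype gives the mother's untransmitted
haplotype. For a son, his haplotype *is* the transmitted maternal one. Every
complete triad therefore yields the three parental haplotypes F (paternal),
M1 (maternal transmitted) and M2 (maternal untransmitted) exactly, by
elementwise integer subtraction (`phase_triads()`); any subtraction falling
outside {0, 1} flags a Mendelian inconsistency and the family is excluded
for that window only.

## Parental haplotype exchangeability and pseudo-siblings

The key modeling assumption is **parental haplotype exchangeability
(PHE)**: in the source population, each of the three X haplotypes carried
by a couple is equally likely to be the one carried by the father. PHE is
strictly weaker than Hardy-Weinberg equilibrium — it holds within each
stratum of an incompletely admixed population, whereas HWE does not — and
it is testable (below).

Under PHE and the null, an affected child is exchangeable with two
*pseudo-siblings* of the same sex:

* boys: the observed son carries M1; the pseudo-brothers carry M2 and F;
* girls: the observed daughter carries {M1, F}; the pseudo-sisters carry
  {M2, F} and {M1, M2}.

Each family becomes one stratum of a conditional logistic regression with
exactly three alternatives, each with prior probability 1/3
(`build_risk_set()`). A family is noninformative precisely when F = M1 =
M2. Using the father's haplotype as a comparator — not just the
untransmitted maternal one, as a pure transmission test would — is where
PHE buys power.

## The likelihood and the test

Let the *codebook* (`build_codebook()`) list the haplotypes observed in
the window with parental frequencies estimated by counting all three
parental haplotypes per phased family with equal weight. Haplotypes with
frequency below the **rarity threshold** (default 0.01) are pooled into a
single aggregate class whose coefficient is a nuisance parameter; the most
frequent common haplotype is the reference. Each alternative is coded as a
dosage vector: a female contributes the count of each haplotype among her
two copies; a male's single haplotype counts as **two** copies under the
default `"double"` coding, equating his risk to a homozygous female's (an
X-inactivation-motivated simplification; `"single"` coding and
sex-restricted fits are available).

The conditional log-likelihood is exact — each stratum contributes
$\eta_{\text{case}} - \log\sum_{j=1}^{3} e^{\eta_j}$ with
$\eta = x^\top\beta$ — and globally concave, so it is maximized by
Newton-Raphson with analytic gradient and Hessian and step-halving
(convergence when the maximal score component falls below 1e-8 or the step
below 1e-10; 50 iterations maximum; |β| > 10 at convergence raises a
separation flag). The global test compares the model with one coefficient
per nonreference common haplotype (plus the rare aggregate) against the
null retaining only the rare-aggregate coefficient:
$\chi^2 = 2(\ell_1 - \ell_0)$ on **(number of common haplotypes − 1)**
degrees of freedom (`pixhap_lrt()`). With all 16 haplotypes of a 4-SNP
window common that is a 15-df test; pooling usually reduces it
substantially.

Numerical notes. The within-stratum dosage total is constant, so one
coefficient is unidentifiable; the reference haplotype absorbs it and the
test p-value is provably invariant to which common haplotype is chosen (we
test this). A model column that never varies within any stratum
contributes nothing to the conditional likelihood; its coefficient is
reported `NA` and the window flagged `degenerate`, while the chi-squared is
still computed from the estimable columns. With fewer than two common
haplotypes the test is undefined and the window errors as degenerate. If
exactly one haplotype is rare it still forms the aggregate class by
itself — the pooling rule is about frequency, not about how many
haplotypes are pooled. When no haplotype is rare, the null model is empty
and its log-likelihood is exactly −n·ln 3.

## Testing PHE and interpreting violations

PHE itself is tested by the same machinery with roles swapped: the
father's haplotype is the "case" and the mother's two haplotypes are the
controls, each alternative carrying one haplotype with dosage 1
(`phe_lrt()`). The test is valid under the global null and the absence of
maternally-mediated effects. A rejection has three candidate explanations,
distinguishable by `phe_sex_decomposition()`, which adds
haplotype-by-offspring-sex interaction columns:

* a true **fetal effect** enriches mothers of affected boys but fathers of
  affected girls, so the parental asymmetry reverses with offspring sex and
  loads on the interaction;
* a **maternally-mediated effect** (or a genuine PHE violation from
  nonrandom mating) enriches mothers regardless of offspring sex and loads
  on the main effects only.

The labels returned are qualitative flags at a configurable level
(default 0.05), not automated conclusions: the decomposition is an
interpretive aid, and distinguishing nonrandom mating from a maternal
mechanism needs external evidence (for instance re-running after excluding
ethnically discordant couples).

## The sliding-window scan and quality diagnostics

`pixhap_scan()` slides a window (default 4 SNPs, adjacent in panel order)
across the filtered panel. SNPs are retained when their parental
minor-allele frequency is *strictly* greater than 0.05 (fathers contribute
one X allele, mothers two) and not on an exclusion list. With S retained
SNPs there are S − 3 windows and the Bonferroni threshold is
0.05/(S − 3); degenerate windows are recorded and skipped. Outputs are a
TSV table, Manhattan data (−log10 p against the position of the window's
first SNP) and QQ data with expected quantiles −log10((i − 0.5)/n).

Because haplotype methods multiply per-SNP call failures, the package
includes a genotype-dependent missingness diagnostic
(`missingness_crosstab()`): for each family role it cross-tabulates the
genotype at one locus against called/missing status at another and applies
a two-sided Fisher exact test to carrier status × missingness. The flag
Bonferroni-combines the four per-role tests rather than pooling roles,
because role-specific missingness confounds a pooled table (hemizygous and
diploid carriers have different carrier rates). Call failure at one locus
that tracks the genotype at a neighbor makes haplotypes informatively
missing and can fabricate strong association signals; windows flagged here
should be excluded and the scan re-run.

## The simulator and what it does (not) emulate

`simulate_triads()` generates triads with PHE holding *by construction*:
three haplotypes drawn i.i.d. from the subpopulation's frequencies are
allocated at random between the parents, maternal transmission is a fair
coin, child sex is Bernoulli(0.5), and affected-child ascertainment is
rejection sampling with weight baseline(subpopulation) × relative risk of
the child's haplotypes. Preset scenarios (`scenario_config()`):

* **null-hwe** — one subpopulation, HWE haplotype frequencies as per-locus
  products with minor-allele frequency 0.3 at each of 4 SNPs ("0000" =
  0.7⁴ = 0.2401, "1100" = 0.0441), no haplotype effect;
* **null-stratified** — equal mixture with a second subpopulation
  (per-locus frequency 0.2) whose baseline risk is 4-fold higher; HWE
  fails in the mixture but PHE holds within families;
* **A** — risk haplotype "1100" with male relative risk 1.5 and
  log-additive female risks (√1.5 per copy);
* **B**/**C** — "1101" additionally harmful (1.2) or protective (1/1.2),
  log-additively.

Power curves vary the summed risk-haplotype frequency while preserving the
"1100":"1101" ratio of 0.0441:0.0189 = 7:3 and rescaling the remaining
haplotypes to total 1 (`rescale_frequencies()`).

Design choices made where the design was genuinely open: the
subpopulation mixing proportion defaults to 0.5 (robustness should hold
for any mix, and 0.5 maximizes the stratification the null must absorb);
scenarios B and C use the log-additive reading of the female one-copy risk
(R_G1 = √R_G2), consistent with scenario A, with a configurable override;
baseline absolute risks are irrelevant under rejection sampling beyond the
between-subpopulation ratio; and reproducibility uses per-dataset seed
substreams (`seed + dataset index`).

The generator emulates the sampling structure of a triad study —
ascertainment on an affected child, hemizygous males, population mixture —
but **not** genotyping error, informative missingness, linkage
disequilibrium beyond what the haplotype frequencies encode,
recombination within windows, multiplex families, or incomplete triads.
Passing simulation tests therefore validates the inferential machinery
under clean data, not robustness to the data-quality pathologies the
missingness diagnostic exists to catch.

## Study sizes used in validation

The packaged validation suite estimates the type-I error over 1000
simulated datasets of 1000 families each (rejection fraction at α = 0.05
expected within 3 binomial standard errors of the nominal level, i.e.
±0.021), power over 200 datasets per design point at sample sizes 100-1000
families, coefficient recovery of ln(1.5)/2 for the scenario-A risk
haplotype over 200 replicates at 1000 families, and PHE p-value uniformity
over 2000 replicates of 500 families (Kolmogorov-Smirnov at α = 0.01). At
500 families and 14-15 df the chi-squared approximation is already
accurate; with substantially fewer informative families per window the LRT
becomes mildly anti-conservative, which is worth remembering when
analyzing small strata.

## Known limitations

Complete triads only (the two-alternative pseudo-brother for boys with one
missing parent, `build_single_pseudo_sib()`, is available but off by
default); no covariate adjustment, robust variances or exact conditional
inference; no EM handling of missing genotypes or mother-daughter dyads;
pseudo-autosomal and X-transposed regions are out of scope (they recombine
with the Y and break the hemizygosity the phasing relies on); windows
assume no recombination among their SNPs, so very wide windows over long
genomic spans are inappropriate.
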