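# Triad simulator for type-I-error and power studies.
#
# Families are generated with PHE holding by construction: three haplotypes
# are drawn i.i.d. from the family's subpopulation frequencies and
# allocated at random between father (one) and mother (two); the maternal
# transmission is a fair coin; child sex is Bernoulli.  Affected-child
# ascertainment is rejection sampling with acceptance probability
# proportional to baseline(subpopulation) x relative risk of the child's
# haplotype(s), so only the between-subpopulation baseline ratio matters.

#' Hardy-Weinberg haplotype frequencies from per-locus minor-allele
#' frequencies
#'
#' Under HWE with no linkage disequilibrium the frequency of a haplotype is
#' the product of its per-locus allele frequencies; e.g. with minor-allele
#' frequency 0.3 at each of 4 loci, "0000" has frequency 0.7^4 = 0.2401 and
#' "1100" has 0.3^2 * 0.7^2 = 0.0441.
#'
#' @param maf per-locus minor-allele frequency, recycled to `n_snps`.
#' @param n_snps number of loci (default 4).
#' @return named numeric vector of `2^n_snps` haplotype frequencies.
#' @export
hwe_hap_frequencies <- function(maf = 0.3, n_snps = 4L) {
  maf <- rep_len(maf, n_snps)
  codes <- seq_len(2^n_snps)
  alleles <- hap_decode(codes, n_snps)
  freq <- apply(alleles, 1L, function(a) prod(ifelse(a == 1L, maf, 1 - maf)))
  stats::setNames(freq, hap_label(codes, n_snps))
}

#' Rescale haplotype frequencies to a target risk-haplotype total
#'
#' Sets the summed frequency of the designated risk haplotypes to
#' `target_total`, preserving their internal ratio, and rescales the
#' remaining haplotypes by a common factor so the total stays 1.
#'
#' @param base_frequencies named frequency vector summing to 1.
#' @param risk_haplotypes character labels of the risk haplotypes.
#' @param target_total their new summed frequency, in (0, 1).
#' @return rescaled named frequency vector.
#' @export
rescale_frequencies <- function(base_frequencies, risk_haplotypes, target_total) {
  if (target_total <= 0 || target_total >= 1)
    pixhap_stop("target_total must lie strictly between 0 and 1",
                "pixhap_config_error")
  stopifnot(all(risk_haplotypes %in% names(base_frequencies)))
  out <- base_frequencies
  risk <- names(out) %in% risk_haplotypes
  out[risk] <- out[risk] / sum(out[risk]) * target_total
  out[!risk] <- out[!risk] / sum(out[!risk]) * (1 - target_total)
  out
}

#' Simulation configuration
#'
#' @param haplotype_frequencies a named frequency vector (one
#'   subpopulation) or a matrix with one column per subpopulation, each
#'   column summing to 1.
#' @param subpop_mix probability a family comes from subpopulation 1
#'   (default 0.5).
#' @param baseline_risk_ratio baseline disease risk of subpopulation 2
#'   relative to subpopulation 1 (default 1; the stratified null uses 4).
#' @param risk_map data frame with columns `haplotype`, `rb` (male
#'   relative risk), `rg1` (one-copy female), `rg2` (two-copy female), or
#'   `NULL` for the global null.
#' @param n_families triads per dataset (default 1000).
#' @param sex_ratio probability the affected child is male (default 0.5).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(haplotype_frequencies, subpop_mix = 0.5,
                       baseline_risk_ratio = 1, risk_map = NULL,
                       n_families = 1000L, sex_ratio = 0.5) {
  if (is.null(dim(haplotype_frequencies)))
    haplotype_frequencies <- cbind(pop1 = haplotype_frequencies)
  sums <- colSums(haplotype_frequencies)
  if (any(abs(sums - 1) > 1e-9))
    pixhap_stop("each subpopulation's haplotype frequencies must sum to 1",
                "pixhap_config_error")
  w <- log2(nrow(haplotype_frequencies))
  if (w != round(w))
    pixhap_stop("frequency vector length must be a power of 2",
                "pixhap_config_error")
  labels <- rownames(haplotype_frequencies)
  if (is.null(labels)) labels <- hap_label(seq_len(2^w), as.integer(w))
  rb <- rg1 <- rg2 <- rep(1, 2^w)
  if (!is.null(risk_map)) {
    idx <- hap_parse(risk_map$haplotype)
    rb[idx] <- risk_map$rb; rg1[idx] <- risk_map$rg1; rg2[idx] <- risk_map$rg2
  }
  structure(
    list(freq = unname(haplotype_frequencies), labels = labels,
         w = as.integer(w), n_subpop = ncol(haplotype_frequencies),
         subpop_mix = subpop_mix, baseline_risk_ratio = baseline_risk_ratio,
         rb = rb, rg1 = rg1, rg2 = rg2,
         n_families = as.integer(n_families), sex_ratio = sex_ratio),
    class = "sim_config")
}

#' Preset simulation scenarios
#'
#' * `"null-hwe"`: one HWE subpopulation (per-locus minor-allele frequency
#'   0.3 over 4 SNPs), no haplotype effect.
#' * `"null-stratified"`: equal mixture of two HWE subpopulations
#'   (per-locus frequencies 0.3 and 0.2) with a 4-fold higher baseline
#'   risk in the second; no haplotype effect.
#' * `"A"`: HWE, risk haplotype "1100" with male relative risk 1.5 and a
#'   log-additive female model (one copy sqrt(1.5), two copies 1.5).
#' * `"B"`: as A plus "1101" with relative risk 1.2 (log-additive).
#' * `"C"`: as A but "1101" protective, relative risk 1/1.2 (log-additive).
#'
#' @param scenario scenario name.
#' @param n_families triads per dataset.
#' @param risk_frequency optional summed frequency of the risk
#'   haplotype(s); frequencies are rescaled with [rescale_frequencies()]
#'   keeping the "1100":"1101" ratio fixed.
#' @return a `sim_config`.
#' @export
scenario_config <- function(scenario = c("null-hwe", "null-stratified",
                                         "A", "B", "C"),
                            n_families = 1000L, risk_frequency = NULL) {
  scenario <- match.arg(scenario)
  f1 <- hwe_hap_frequencies(0.3, 4L)
  if (scenario == "null-stratified") {
    f2 <- hwe_hap_frequencies(0.2, 4L)
    return(sim_config(cbind(pop1 = f1, pop2 = f2), subpop_mix = 0.5,
                      baseline_risk_ratio = 4, n_families = n_families))
  }
  risk_map <- switch(scenario,
    "null-hwe" = NULL,
    "A" = data.frame(haplotype = "1100", rb = 1.5,
                     rg1 = sqrt(1.5), rg2 = 1.5),
    "B" = data.frame(haplotype = c("1100", "1101"),
                     rb = c(1.5, 1.2), rg1 = sqrt(c(1.5, 1.2)),
                     rg2 = c(1.5, 1.2)),
    "C" = data.frame(haplotype = c("1100", "1101"),
                     rb = c(1.5, 1 / 1.2), rg1 = sqrt(c(1.5, 1 / 1.2)),
                     rg2 = c(1.5, 1 / 1.2)))
  if (!is.null(risk_frequency)) {
    risk_haps <- if (scenario %in% c("B", "C")) c("1100", "1101") else "1100"
    f1 <- rescale_frequencies(f1, risk_haps, risk_frequency)
  }
  sim_config(cbind(pop1 = f1), risk_map = risk_map, n_families = n_families)
}

# Draw n accepted (affected, ascertained) families as haplotype codes.
# Returns list(F, M1, M2 integer code vectors, male logical, subpop).
draw_families <- function(config) {
  n <- config$n_families
  baseline <- c(1, config$baseline_risk_ratio)[seq_len(config$n_subpop)]
  max_w <- max(baseline) *
    max(max(config$rb), max(config$rg2), max(config$rg1)^2)
  out_F <- out_M1 <- out_M2 <- integer(0)
  out_male <- logical(0); out_sub <- integer(0)
  need <- n
  while (need > 0L) {
    m <- max(2L * need, 256L)
    sub <- if (config$n_subpop == 1L) rep(1L, m)
      else 1L + (stats::runif(m) >= config$subpop_mix)
    draws <- matrix(0L, m, 3L)
    for (s in seq_len(config$n_subpop)) {
      rows <- which(sub == s)
      if (length(rows) == 0L) next
      draws[rows, ] <- sample.int(2^config$w, 3L * length(rows),
                                  replace = TRUE, prob = config$freq[, s])
    }
    # i.i.d. draws are already exchangeable: column 1 = father,
    # column 2 = transmitted maternal, column 3 = nontransmitted.
    male <- stats::runif(m) < config$sex_ratio
    rr <- ifelse(male, config$rb[draws[, 2L]],
                 ifelse(draws[, 1L] == draws[, 2L],
                        config$rg2[draws[, 2L]],
                        config$rg1[draws[, 1L]] * config$rg1[draws[, 2L]]))
    acc <- stats::runif(m) < baseline[sub] * rr / max_w
    take <- which(acc)[seq_len(min(need, sum(acc)))]
    out_F <- c(out_F, draws[take, 1L]); out_M1 <- c(out_M1, draws[take, 2L])
    out_M2 <- c(out_M2, draws[take, 3L])
    out_male <- c(out_male, male[take]); out_sub <- c(out_sub, sub[take])
    need <- n - length(out_F)
  }
  list(F = out_F, M1 = out_M1, M2 = out_M2, male = out_male, subpop = out_sub)
}

#' Draw one ascertained triad, phased
#'
#' @param config a `sim_config`.
#' @return a single-triad list as from [phase_triad()].
#' @export
draw_family <- function(config) {
  config$n_families <- 1L
  d <- draw_families(config)
  list(family_id = "fam1",
       paternal = hap_decode(d$F, config$w)[1L, ],
       mat_trans = hap_decode(d$M1, config$w)[1L, ],
       mat_untrans = hap_decode(d$M2, config$w)[1L, ],
       child_sex = if (d$male) "male" else "female")
}

#' Simulate a genotype-level triad dataset
#'
#' Draws `n_families` affected triads and degrades them to observable
#' (phase-ambiguous) genotypes: mothers' and daughters' haplotypes are
#' summed into copy counts.  Downstream analysis must re-phase, exercising
#' the full pipeline.  Deterministic given the RNG state; call
#' `set.seed()` first for reproducibility.
#'
#' @param config a `sim_config`.
#' @return a `triad_set`; the generating phased truth is attached as
#'   attribute `"truth"` (a `phased_triads` object).
#' @export
simulate_triads <- function(config) {
  d <- draw_families(config)
  w <- config$w
  Fh <- hap_decode(d$F, w); M1 <- hap_decode(d$M1, w); M2 <- hap_decode(d$M2, w)
  n <- length(d$F)
  child <- M1
  child[!d$male, ] <- M1[!d$male, , drop = FALSE] + Fh[!d$male, , drop = FALSE]
  ids <- paste0("fam", seq_len(n))
  ts <- triad_set(ids, father = Fh, mother = M1 + M2, child = child,
                  child_sex = ifelse(d$male, "male", "female"))
  attr(ts, "truth") <- structure(
    list(family_id = ids, paternal = Fh, mat_trans = M1, mat_untrans = M2,
         child_sex = ifelse(d$male, "male", "female"), map = ts$map,
         n_missing = 0L, n_mendelian = 0L, mendelian_families = character(0)),
    class = "phased_triads")
  ts
}

#' Monte-Carlo study of the haplotype LRT
#'
#' Simulates `n_datasets` independent datasets under a preset scenario,
#' runs the full pipeline on each (re-phase, codebook with the rare
#' threshold, LRT under male `"double"` coding), and reports the rejection
#' fraction at level `alpha` with its binomial standard error, plus the
#' mean and SD of the risk-haplotype coefficient where one is defined.
#'
#' @param scenario passed to [scenario_config()].
#' @param n_datasets number of simulated datasets.
#' @param n_families triads per dataset.
#' @param alpha nominal test level (default 0.05).
#' @param seed integer seed; dataset d uses substream `seed + d` so runs
#'   parallelize and reproduce exactly.
#' @param risk_frequency optional risk-haplotype frequency (power curves).
#' @param rare_threshold parental-frequency pooling threshold.
#' @return a list: `rejection_rate`, `se`, `p_values`, `n_failed`,
#'   `beta_risk` (per-dataset "1100" coefficient, `NA` under the nulls),
#'   and the arguments used.
#' @export
run_study <- function(scenario = "null-hwe", n_datasets = 100L,
                      n_families = 1000L, alpha = 0.05, seed = 1L,
                      risk_frequency = NULL, rare_threshold = 0.01) {
  config <- scenario_config(scenario, n_families = n_families,
                            risk_frequency = risk_frequency)
  p_values <- rep(NA_real_, n_datasets)
  beta_risk <- rep(NA_real_, n_datasets)
  n_failed <- 0L
  for (d in seq_len(n_datasets)) {
    set.seed(seed + d)
    res <- tryCatch({
      ts <- simulate_triads(config)
      ph <- phase_triads(ts)
      cb <- build_codebook(ph, threshold = rare_threshold)
      lrt <- pixhap_lrt(ph, cb, coding = "double")
      b <- lrt$fit_alt$coefficients
      list(p = lrt$p_value,
           beta = if ("1100" %in% names(b)) unname(b["1100"]) else NA_real_)
    }, pixhap_error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    p_values[d] <- res$p
    beta_risk[d] <- res$beta
  }
  ok <- !is.na(p_values)
  rate <- mean(p_values[ok] < alpha)
  list(scenario = scenario, n_datasets = n_datasets, n_families = n_families,
       alpha = alpha, seed = seed, risk_frequency = risk_frequency,
       rejection_rate = rate,
       se = sqrt(rate * (1 - rate) / sum(ok)),
       p_values = p_values, beta_risk = beta_risk, n_failed = n_failed)
}
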