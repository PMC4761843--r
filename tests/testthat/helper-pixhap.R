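# Shared fixtures: all generated in code.

# A phased_triads object from explicit haplotype code vectors.
phased_from_codes <- function(f, m1, m2, sex, w = 4L) {
  n <- length(f)
  structure(
    list(family_id = paste0("fam", seq_len(n)),
         paternal = hap_decode(f, w),
         mat_trans = hap_decode(m1, w),
         mat_untrans = hap_decode(m2, w),
         child_sex = sex,
         map = data.frame(snp = paste0("snp", 1:w), chr = "X",
                          pos = 5000L * (1:w)),
         n_missing = 0L, n_mendelian = 0L,
         mendelian_families = character(0)),
    class = "phased_triads")
}

# Single-triad list (phase_triad() output shape) from allele vectors.
single_phased <- function(f, m1, m2, sex, id = "fam1") {
  list(family_id = id, paternal = f, mat_trans = m1, mat_untrans = m2,
       child_sex = sex)
}

# Phased triads with every one of the 2^w haplotypes common: families
# cycle deterministically through all codes so each frequency is 1/2^w.
phased_all_common <- function(n = 320L, w = 4L) {
  k <- 2^w
  i <- seq_len(n) - 1L
  phased_from_codes(i %% k + 1L, (i + 1L) %% k + 1L, (i + 5L) %% k + 1L,
                    rep(c("male", "female"), length.out = n), w = w)
}

# Null-simulated phased triads (PHE holds, no haplotype effect).
null_phased <- function(n = 500L, seed = 1L) {
  set.seed(seed)
  phase_triads(simulate_triads(scenario_config("null-hwe", n_families = n)))
}

# Generator with a maternally-mediated effect: ascertainment depends on
# the mother's copies of the risk haplotype, not on transmission.
maternal_effect_phased <- function(n = 500L, risk = "1100", rr = 2) {
  freq <- hwe_hap_frequencies(0.3, 4L)
  risk_code <- hap_parse(risk)
  out <- NULL
  while (is.null(out) || length(out$f) < n) {
    m <- 4L * n
    draws <- matrix(sample.int(16L, 3L * m, replace = TRUE, prob = freq),
                    ncol = 3L)
    copies <- (draws[, 2L] == risk_code) + (draws[, 3L] == risk_code)
    acc <- runif(m) < rr^copies / rr^2
    out <- list(f = c(out$f, draws[acc, 1L]),
                m1 = c(out$m1, draws[acc, 2L]),
                m2 = c(out$m2, draws[acc, 3L]))
  }
  phased_from_codes(out$f[1:n], out$m1[1:n], out$m2[1:n],
                    sample(c("male", "female"), n, replace = TRUE))
}
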