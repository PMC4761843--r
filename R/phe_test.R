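# Testing parental haplotype exchangeability (PHE).
#
# Under PHE each of the three haplotypes carried by a couple is equally
# likely to be the father's, so treating the father's haplotype as the
# "case" and the mother's two haplotypes as "controls" in the same
# conditional-logistic machinery gives a diagnostic test: asymmetry between
# parents rejects.  Rejection can reflect a true PHE violation (nonrandom
# mating), a maternally-mediated effect, or a genuine fetal effect; the
# offspring-sex decomposition helps distinguish the last, since a
# transmitted-haplotype effect enriches mothers of affected boys but
# fathers of affected girls.

#' PHE risk set for one phased triad
#'
#' @param phased a single-triad list from [phase_triad()].
#' @return a `risk_set` with three single-haplotype alternatives; the
#'   father's haplotype is the case (listed first).  Dosage coding is
#'   `"single"`: every alternative carries exactly one haplotype.
#' @export
phe_risk_set <- function(phased) {
  if (!is_informative(phased))
    pixhap_stop("noninformative family: all three parental haplotypes identical",
                "pixhap_noninformative_error")
  alts <- list(matrix(phased$paternal, nrow = 1L),
               matrix(phased$mat_trans, nrow = 1L),
               matrix(phased$mat_untrans, nrow = 1L))
  key <- vapply(alts[2:3], function(a) paste(hap_encode(a), collapse = ","), "")
  alts[2:3] <- alts[2:3][order(key)]
  structure(
    list(family_id = phased$family_id, child_sex = phased$child_sex,
         alternatives = alts, case_index = 1L),
    class = "risk_set")
}

# Vectorized PHE alternatives: father as case, the two maternal haplotypes
# as controls, each alternative carrying one haplotype with weight 1.
phe_alternatives <- function(phased) {
  keep <- is_informative(phased)
  codes <- phased_codes(phased)[keep, , drop = FALSE]
  n <- nrow(codes)
  na2 <- rep(NA_integer_, n)
  list(alts = list(cbind(codes[, "F"], na2),
                   cbind(codes[, "M1"], na2),
                   cbind(codes[, "M2"], na2)),
       male = rep(FALSE, n), n = n,
       family_id = phased$family_id[keep],
       child_male = phased$child_sex[keep] == "male")
}

#' Likelihood-ratio test of parental haplotype exchangeability
#'
#' Fits the conditional-logistic model to the PHE risk sets (father =
#' case) with a coefficient per nonreference common haplotype plus the
#' pooled rare group, against the null with the rare-group coefficient
#' only; df = number of common haplotypes - 1.  Valid under the global
#' null of no haplotype effects and no maternally-mediated effects.
#'
#' @param phased a `phased_triads` object.
#' @param codebook a `hap_codebook` for the same window.
#' @return an `lrt_result`.
#' @export
phe_lrt <- function(phased, codebook) {
  ra <- phe_alternatives(phased)
  if (ra$n == 0L)
    pixhap_stop("no informative strata", "pixhap_degenerate_window_error")
  dm <- dosage_matrix(ra, codebook, male_weight = 1)
  X <- dm$X
  fit_alt0 <- fit_clr_matrix(X, dm$n, dm$nalt)
  Xn <- X[, colnames(X) == "rare", drop = FALSE]
  fit_null0 <- fit_clr_matrix(Xn, dm$n, dm$nalt)
  lrt_from_fits(wrap_fit(fit_alt0, colnames(X), "alternative", "single"),
                wrap_fit(fit_null0, colnames(Xn), "null", "single"),
                df = length(codebook$common) - 1L,
                window_id = codebook$window_id)
}

wrap_fit <- function(fit, cols, model, coding) {
  structure(
    list(coefficients = stats::setNames(fit$coef, cols),
         log_likelihood = fit$loglik, converged = fit$converged,
         n_strata = fit$n_strata, iterations = fit$iterations,
         separation = fit$separation,
         degenerate_columns = cols[!fit$estimable],
         model = model, coding = coding),
    class = "clr_fit")
}

#' Offspring-sex decomposition of a PHE signal
#'
#' Augments the PHE model with haplotype-by-offspring-sex interaction
#' columns and tests them with an LRT against the main-effects PHE model.
#' A fetal (transmitted-haplotype) effect reverses the direction of
#' parental asymmetry between families with affected boys and girls, so it
#' loads on the interaction; a maternal effect or a population-level PHE
#' violation produces the same asymmetry in both and loads on the main
#' effects.
#'
#' @inheritParams phe_lrt
#' @param alpha flagging level for the qualitative interpretation (default
#'   0.05).
#' @return a list: `interaction` (`lrt_result` for the sex interaction),
#'   `main` (`lrt_result`, the main-effects PHE test), and
#'   `interpretation`, one of `"consistent with fetal effect"`,
#'   `"consistent with maternal effect or PHE violation"`, or
#'   `"no significant asymmetry"`.
#' @export
phe_sex_decomposition <- function(phased, codebook, alpha = 0.05) {
  ra <- phe_alternatives(phased)
  if (ra$n == 0L)
    pixhap_stop("no informative strata", "pixhap_degenerate_window_error")
  if (length(unique(ra$child_male)) < 2L)
    pixhap_stop("both offspring sexes are required for the decomposition",
                "pixhap_degenerate_window_error")
  dm <- dosage_matrix(ra, codebook, male_weight = 1)
  X <- dm$X
  sex_ind <- rep(as.numeric(ra$child_male), each = dm$nalt)
  Xint <- X * sex_ind
  colnames(Xint) <- paste0(colnames(X), ":boy")
  Xfull <- cbind(X, Xint)

  fit_full <- fit_clr_matrix(Xfull, dm$n, dm$nalt)
  fit_main <- fit_clr_matrix(X, dm$n, dm$nalt)
  fit_null <- fit_clr_matrix(X[, colnames(X) == "rare", drop = FALSE],
                             dm$n, dm$nalt)

  interaction <- lrt_from_fits(
    wrap_fit(fit_full, colnames(Xfull), "alternative", "single"),
    wrap_fit(fit_main, colnames(X), "null", "single"),
    df = ncol(Xint), window_id = codebook$window_id)
  main <- lrt_from_fits(
    wrap_fit(fit_main, colnames(X), "alternative", "single"),
    wrap_fit(fit_null, colnames(X)[colnames(X) == "rare"], "null", "single"),
    df = length(codebook$common) - 1L, window_id = codebook$window_id)

  interpretation <-
    if (interaction$p_value < alpha) "consistent with fetal effect"
    else if (main$p_value < alpha) "consistent with maternal effect or PHE violation"
    else "no significant asymmetry"
  list(interaction = interaction, main = main,
       interpretation = interpretation)
}
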