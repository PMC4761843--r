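# Pseudo-sibling risk sets.
#
# Conditioning is on the family and on the three parental haplotypes
# {F, M1, M2}.  Under the null and parental haplotype exchangeability each
# of three same-sex children the parents could have produced is equally
# likely, so the observed affected child is compared to two pseudo-siblings
# in a 3-alternative conditional-logistic stratum:
#   boys:  case {M1};   pseudo-brothers {M2} and {F}
#   girls: case {M1,F}; pseudo-sisters  {M2,F} and {M1,M2}

#' Build the pseudo-sibling risk set for one phased triad
#'
#' @param phased a single-triad list as returned by [phase_triad()] (fields
#'   `paternal`, `mat_trans`, `mat_untrans`, `child_sex`).
#' @return an object of class `risk_set`: `alternatives` is a list of
#'   exactly 3 haplotype multisets (matrices with one row per carried
#'   haplotype), `case_index` marks the observed child.  The case is listed
#'   first; the two pseudo-sibling alternatives are ordered
#'   lexicographically for reproducibility (the conditional likelihood is
#'   invariant to this order).
#' @export
build_risk_set <- function(phased) {
  if (!is_informative(phased))
    pixhap_stop("noninformative family: all three parental haplotypes identical",
                "pixhap_noninformative_error")
  f <- phased$paternal; m1 <- phased$mat_trans; m2 <- phased$mat_untrans
  if (phased$child_sex == "male") {
    alts <- list(rbind(m1), rbind(m2), rbind(f))
  } else {
    alts <- list(rbind(m1, f), rbind(m2, f), rbind(m1, m2))
  }
  alts <- lapply(alts, function(a) {
    a <- a[order(hap_encode(a)), , drop = FALSE]
    dimnames(a) <- NULL
    a
  })
  key <- vapply(alts[2:3], function(a) paste(hap_encode(a), collapse = ","), "")
  alts[2:3] <- alts[2:3][order(key)]
  structure(
    list(family_id = phased$family_id, child_sex = phased$child_sex,
         alternatives = alts, case_index = 1L),
    class = "risk_set")
}

#' Two-alternative risk set for an affected son with one missing parent
#'
#' When the father is missing, the son's transmitted haplotype is compared
#' to the mother's nontransmitted haplotype (obtained by subtraction); when
#' the mother is missing, to the father's single haplotype.  Disabled by
#' default in the scan; enable with `allow_missing_parent_boys`.
#'
#' @param son_haplotype integer 0/1 vector, the affected son's haplotype.
#' @param mother_genotype integer copy-count vector, or `NULL` if the
#'   mother is the missing parent.
#' @param father_haplotype integer 0/1 vector, or `NULL` if the father is
#'   the missing parent.
#' @param family_id identifier.
#' @return a `risk_set` with 2 alternatives (case first), or `NULL` when
#'   the case and control haplotypes coincide (noninformative).
#' @export
build_single_pseudo_sib <- function(son_haplotype, mother_genotype = NULL,
                                    father_haplotype = NULL,
                                    family_id = "fam") {
  if (is.null(mother_genotype) == is.null(father_haplotype))
    pixhap_stop("exactly one parent must be available", "pixhap_pedigree_error")
  if (!is.null(mother_genotype)) {
    control <- mother_genotype - son_haplotype
    if (any(control < 0L | control > 1L))
      pixhap_stop(sprintf("family %s: mother minus son outside {0,1}", family_id),
                  "pixhap_mendelian_error")
  } else {
    control <- father_haplotype
  }
  if (all(control == son_haplotype)) return(NULL)
  structure(
    list(family_id = family_id, child_sex = "male",
         alternatives = list(matrix(son_haplotype, nrow = 1L),
                             matrix(control, nrow = 1L)),
         case_index = 1L),
    class = "risk_set")
}

# Vectorized alternatives for all informative families in a phased window.
#
# Returns a list with, per alternative j in 1..3, an n x 2 matrix of
# haplotype codes (second column NA for males, who carry one haplotype).
# Alternative 1 is always the observed case.
risk_alternatives <- function(phased) {
  keep <- is_informative(phased)
  codes <- phased_codes(phased)[keep, , drop = FALSE]
  male <- phased$child_sex[keep] == "male"
  n <- nrow(codes)
  a1 <- cbind(codes[, "M1"], ifelse(male, NA_integer_, codes[, "F"]))
  a2 <- cbind(codes[, "M2"], ifelse(male, NA_integer_, codes[, "F"]))
  a3 <- cbind(ifelse(male, codes[, "F"], codes[, "M1"]),
              ifelse(male, NA_integer_, codes[, "M2"]))
  list(alts = list(a1, a2, a3), male = male, n = n,
       family_id = phased$family_id[keep])
}
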