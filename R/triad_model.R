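# Triad containers and deterministic X-chromosome phasing.
#
# On the X there is no phase ambiguity for complete case-parent triads:
# fathers and sons carry a single haplotype that is observed directly, a
# daughter's maternal haplotype is her genotype minus the father's
# haplotype, and the mother's second haplotype is her genotype minus the
# transmitted one.  Phasing is therefore elementwise integer subtraction;
# any result outside {0,1} flags a Mendelian inconsistency.

#' Construct a set of case-parent triads
#'
#' Genotypes are minor-allele copy counts: fathers and sons are hemizygous
#' (0/1), mothers and daughters carry two X copies (0/1/2).  `NA` marks a
#' missing call.
#'
#' @param family_id character vector of family identifiers.
#' @param father,mother,child integer matrices (families x loci) of
#'   minor-allele counts; `child` rows for male children must not exceed 1.
#' @param child_sex character vector, `"male"` or `"female"` per family.
#' @param map data frame describing the loci, with columns `snp`, `chr`,
#'   `pos` (1-based physical positions).  Defaults to synthetic positions.
#' @return an object of class `triad_set`.
#' @export
triad_set <- function(family_id, father, mother, child, child_sex, map = NULL) {
  father <- as.matrix(father); mother <- as.matrix(mother); child <- as.matrix(child)
  n <- length(family_id)
  L <- ncol(father)
  stopifnot(
    nrow(father) == n, nrow(mother) == n, nrow(child) == n,
    ncol(mother) == L, ncol(child) == L,
    all(child_sex %in% c("male", "female"))
  )
  if (any(father > 1L, na.rm = TRUE))
    pixhap_stop("fathers are hemizygous: copy counts must be 0 or 1",
                "pixhap_sex_code_error")
  male <- child_sex == "male"
  if (any(child[male, , drop = FALSE] > 1L, na.rm = TRUE))
    pixhap_stop("male children are hemizygous: copy counts must be 0 or 1",
                "pixhap_sex_code_error")
  if (is.null(map))
    map <- data.frame(snp = paste0("snp", seq_len(L)), chr = "X",
                      pos = seq_len(L) * 5000L)
  structure(
    list(family_id = as.character(family_id),
         father = father, mother = mother, child = child,
         child_sex = as.character(child_sex), map = map),
    class = "triad_set")
}

#' @export
print.triad_set <- function(x, ...) {
  cat(sprintf("triad_set: %d families x %d X-linked SNPs (%d male, %d female children)\n",
              length(x$family_id), ncol(x$father),
              sum(x$child_sex == "male"), sum(x$child_sex == "female")))
  invisible(x)
}

#' Number of families and loci in a triad set
#' @param x a `triad_set`.
#' @return integer.
#' @export
n_families <- function(x) length(x$family_id)

#' Restrict a triad set to a subset of loci and/or families
#'
#' @param x a `triad_set`.
#' @param loci integer or logical index over loci (map order preserved).
#' @param families integer or logical index over families.
#' @return a `triad_set`.
#' @export
subset_triads <- function(x, loci = NULL, families = NULL) {
  if (!is.null(loci)) {
    x$father <- x$father[, loci, drop = FALSE]
    x$mother <- x$mother[, loci, drop = FALSE]
    x$child  <- x$child[, loci, drop = FALSE]
    x$map    <- x$map[loci, , drop = FALSE]
  }
  if (!is.null(families)) {
    x$family_id <- x$family_id[families]
    x$father <- x$father[families, , drop = FALSE]
    x$mother <- x$mother[families, , drop = FALSE]
    x$child  <- x$child[families, , drop = FALSE]
    x$child_sex <- x$child_sex[families]
  }
  x
}

#' Phase all triads in a window
#'
#' Reconstructs, for every family, the father's haplotype (F), the
#' maternally transmitted haplotype (M1) and the maternal nontransmitted
#' haplotype (M2) by elementwise subtraction.  Families with a missing call
#' or a Mendelian inconsistency anywhere in the window are dropped (the
#' exclusion is local to this window) and counted in the result.
#'
#' @param triads a `triad_set`, already restricted to the window of
#'   interest (use [subset_triads()] to pick a window).
#' @return an object of class `phased_triads`: matrices `paternal`,
#'   `mat_trans`, `mat_untrans` (families x loci), `child_sex`,
#'   `family_id`, the window `map`, and counts `n_missing`, `n_mendelian`
#'   of families excluded.
#' @export
phase_triads <- function(triads) {
  stopifnot(inherits(triads, "triad_set"))
  male <- triads$child_sex == "male"
  f  <- triads$father
  m1 <- triads$child
  # daughters: maternal transmitted = child - father
  m1[!male, ] <- triads$child[!male, , drop = FALSE] - f[!male, , drop = FALSE]
  m2 <- triads$mother - m1

  miss <- rowSums(is.na(f)) + rowSums(is.na(triads$mother)) +
    rowSums(is.na(triads$child)) > 0L
  bad <- !miss &
    (rowSums(m1 < 0L | m1 > 1L) + rowSums(m2 < 0L | m2 > 1L) +
       rowSums(f < 0L | f > 1L) > 0L)
  keep <- !miss & !bad

  structure(
    list(family_id = triads$family_id[keep],
         paternal = f[keep, , drop = FALSE],
         mat_trans = m1[keep, , drop = FALSE],
         mat_untrans = m2[keep, , drop = FALSE],
         child_sex = triads$child_sex[keep],
         map = triads$map,
         n_missing = sum(miss), n_mendelian = sum(bad),
         mendelian_families = triads$family_id[bad]),
    class = "phased_triads")
}

#' @export
print.phased_triads <- function(x, ...) {
  cat(sprintf(
    "phased_triads: %d families over %d loci (%d dropped missing, %d dropped Mendelian)\n",
    length(x$family_id), ncol(x$paternal), x$n_missing, x$n_mendelian))
  invisible(x)
}

#' Phase a single triad
#'
#' Strict single-family interface: errors rather than drops.
#'
#' @param father,mother,child integer genotype vectors (minor-allele counts).
#' @param child_sex `"male"` or `"female"`.
#' @param family_id identifier for messages.
#' @return a list with `paternal`, `mat_trans`, `mat_untrans` indicator
#'   vectors and `child_sex`.
#' @export
phase_triad <- function(father, mother, child, child_sex, family_id = "fam") {
  if (anyNA(father) || anyNA(mother) || anyNA(child))
    pixhap_stop(sprintf("family %s: missing genotype call in window", family_id),
                "pixhap_missing_genotype_error")
  ph <- phase_triads(triad_set(family_id, rbind(father), rbind(mother),
                               rbind(child), child_sex))
  if (ph$n_mendelian > 0L)
    pixhap_stop(sprintf("family %s: Mendelian inconsistency in window", family_id),
                "pixhap_mendelian_error")
  list(family_id = family_id,
       paternal = ph$paternal[1L, ],
       mat_trans = ph$mat_trans[1L, ],
       mat_untrans = ph$mat_untrans[1L, ],
       child_sex = child_sex)
}

#' Which phased families are informative?
#'
#' A family is noninformative if and only if all three parental haplotypes
#' are identical, in which case the observed child and both pseudo-siblings
#' coincide.
#'
#' @param phased a `phased_triads` object, or a single-triad list from
#'   [phase_triad()].
#' @return logical vector, one entry per family.
#' @export
is_informative <- function(phased) {
  if (!inherits(phased, "phased_triads")) {
    return(!(all(phased$paternal == phased$mat_trans) &&
               all(phased$mat_trans == phased$mat_untrans)))
  }
  same <- rowSums(phased$paternal != phased$mat_trans) == 0L &
    rowSums(phased$mat_trans != phased$mat_untrans) == 0L
  !same
}

# Integer haplotype codes for a phased window: n x 3 matrix (F, M1, M2).
phased_codes <- function(phased) {
  cbind(F = hap_encode(phased$paternal),
        M1 = hap_encode(phased$mat_trans),
        M2 = hap_encode(phased$mat_untrans))
}
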