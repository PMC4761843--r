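# Haplotype encoding and shared condition classes.
#
# A haplotype over W biallelic loci is a vector of 0/1 minor-allele
# indicators.  Internally haplotypes are stored as 1-based integer codes
# 1..2^W obtained by reading the indicator vector as a binary number
# (most significant bit = first locus), so "1100" over 4 loci has code
# 0b1100 + 1 = 13.

#' Encode haplotype indicator rows as integer codes
#'
#' @param alleles integer matrix (rows = haplotypes, columns = loci) of 0/1
#'   minor-allele indicators, or a single vector.
#' @return integer vector of 1-based codes in `1:2^W`.
#' @seealso [hap_decode()], [hap_label()]
#' @export
hap_encode <- function(alleles) {
  if (is.null(dim(alleles))) alleles <- matrix(alleles, nrow = 1L)
  w <- ncol(alleles)
  stopifnot(w >= 1L, all(alleles %in% c(0L, 1L)))
  as.integer(alleles %*% 2^((w - 1L):0)) + 1L
}

#' Decode integer haplotype codes to indicator rows
#'
#' @param codes integer vector of 1-based codes.
#' @param w window width (number of loci).
#' @return integer matrix with `length(codes)` rows and `w` columns.
#' @export
hap_decode <- function(codes, w) {
  stopifnot(all(codes >= 1L), all(codes <= 2^w))
  x <- codes - 1L
  out <- matrix(0L, length(codes), w)
  for (j in w:1) {
    out[, j] <- x %% 2L
    x <- x %/% 2L
  }
  out
}

#' Human-readable haplotype labels ("1100" style)
#'
#' @inheritParams hap_decode
#' @return character vector, one 0/1 string per code.
#' @export
hap_label <- function(codes, w) {
  m <- hap_decode(codes, w)
  apply(m, 1L, paste0, collapse = "")
}

#' Parse "1100"-style labels back to codes
#'
#' @param labels character vector of 0/1 strings of equal width.
#' @return integer codes.
#' @export
hap_parse <- function(labels) {
  w <- unique(nchar(labels))
  stopifnot(length(w) == 1L)
  m <- t(vapply(strsplit(labels, ""), function(s) as.integer(s), integer(w)))
  hap_encode(m)
}

# Condition constructor: all package errors are classed so callers can
# distinguish Mendelian inconsistencies, missing calls, degeneracies, etc.
pixhap_stop <- function(msg, class, call = sys.call(-1L)) {
  stop(errorCondition(msg, class = c(class, "pixhap_error"), call = call))
}

pixhap_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "pixhap_warning")))
}
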