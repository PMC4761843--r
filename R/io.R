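# PED/MAP readers and writers.
#
# PED: FID IID PAT MAT SEX PHENO then two allele columns per SNP; "0" is
# the missing allele code.  MAP: chromosome, SNP id, genetic distance,
# physical position.  Families are resolved into father/mother/affected
# child triads through the PAT/MAT links; the affected child is the first
# offspring with PHENO == 2.  Male X genotypes are accepted either
# homozygous-coded ("A A", the common convention) or single-allele coded
# ("A 0"); a genuinely heterozygous male X call is an error.  Genotypes
# are normalized to minor-allele copy counts, the minor allele being the
# less frequent allele among parental X chromosomes (ties at 0.5 broken
# toward the lexicographically smaller allele).

#' Read case-parent triads from PED/MAP files
#'
#' @param ped_path path to a whitespace-delimited PED file.
#' @param map_path path to the matching MAP file; only X-chromosome
#'   variants (`chr` of "X", "23" or "chrX") are accepted.
#' @return a `triad_set` of minor-allele copy counts, with the minor
#'   allele per locus recorded in `map$minor`.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chr", "snp", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  if (!all(map$chr %in% c("X", "23", "chrX")))
    pixhap_stop("only X-chromosome variants are supported",
                "pixhap_format_error")
  L <- nrow(map)
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L + 2L * L)
    pixhap_stop(sprintf("PED has %d columns; expected %d for %d SNPs",
                        ncol(ped), 6L + 2L * L, L), "pixhap_format_error")
  names(ped)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(L) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(L), drop = FALSE])

  is_parent <- ped$pat == "0" & ped$mat == "0"
  # affected children with both parents present in the file
  key <- paste(ped$fid, ped$iid)
  kid <- which(!is_parent & ped$pheno == "2" &
                 paste(ped$fid, ped$pat) %in% key &
                 paste(ped$fid, ped$mat) %in% key)
  if (length(kid) == 0L)
    pixhap_stop("no resolvable affected case-parent triads",
                "pixhap_pedigree_error")
  kid <- kid[!duplicated(ped$fid[kid])]   # first affected child per family
  fa_row <- match(paste(ped$fid[kid], ped$pat[kid]), key)
  mo_row <- match(paste(ped$fid[kid], ped$mat[kid]), key)
  if (any(ped$sex[fa_row] != "1") || any(ped$sex[mo_row] != "2"))
    pixhap_stop("PAT/MAT links disagree with SEX codes",
                "pixhap_pedigree_error")
  child_sex <- ifelse(ped$sex[kid] == "1", "male", "female")

  # minor allele per locus from parental X chromosomes
  minor <- character(L)
  for (j in seq_len(L)) {
    als <- c(a1[fa_row, j], a1[mo_row, j], a2[mo_row, j])
    als <- als[als != "0"]
    ua <- sort(unique(als))
    # monomorphic / all-missing loci have no minor allele: count 0 copies
    if (length(ua) <= 1L) { minor[j] <- ""; next }
    cnt <- table(factor(als, levels = ua))
    minor[j] <- if (cnt[[1L]] == cnt[[2L]]) ua[1L]
      else ua[which.min(cnt)]
  }

  count_copies <- function(rows, hemizygous) {
    g <- matrix(NA_integer_, length(rows), L)
    for (j in seq_len(L)) {
      x1 <- a1[rows, j]; x2 <- a2[rows, j]
      if (hemizygous) {
        het <- x1 != "0" & x2 != "0" & x1 != x2
        if (any(het))
          pixhap_stop(sprintf(
            "heterozygous male X call at %s (family %s)", map$snp[j],
            ped$fid[rows[which(het)[1L]]]), "pixhap_sex_code_error")
        al <- ifelse(x1 != "0", x1, x2)     # accepts "A A", "A 0", "0 A"
        g[, j] <- ifelse(al == "0", NA_integer_,
                         as.integer(al == minor[j]))
      } else {
        miss <- x1 == "0" | x2 == "0"
        g[, j] <- ifelse(miss, NA_integer_,
                         (x1 == minor[j]) + (x2 == minor[j]))
      }
    }
    g
  }

  male <- child_sex == "male"
  child <- matrix(NA_integer_, length(kid), L)
  if (any(male))
    child[male, ] <- count_copies(kid[male], hemizygous = TRUE)
  if (any(!male))
    child[!male, ] <- count_copies(kid[!male], hemizygous = FALSE)
  map_out <- data.frame(snp = map$snp, chr = "X", pos = map$pos,
                        minor = minor)
  triad_set(family_id = ped$fid[kid],
            father = count_copies(fa_row, hemizygous = TRUE),
            mother = count_copies(mo_row, hemizygous = FALSE),
            child = child, child_sex = child_sex, map = map_out)
}

#' Write a triad set as PED/MAP files
#'
#' Alleles are written as "A" (major) and "B" (minor); hemizygous males
#' are written homozygous-coded; missing calls as "0 0".
#'
#' @param triads a `triad_set`.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(triads, ped_path, map_path) {
  L <- ncol(triads$father)
  utils::write.table(
    data.frame(chr = "X", snp = triads$map$snp, cm = 0, pos = triads$map$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  allele_pair <- function(g, hemizygous) {
    # g: copy count or NA -> "a1 a2"
    ifelse(is.na(g), "0 0",
           ifelse(g == 0L, "A A", ifelse(g == 1L & !hemizygous, "A B",
                                         "B B")))
  }
  fmt_row <- function(fid, iid, pat, mat, sex, g, hemizygous)
    paste(fid, iid, pat, mat, sex, 2, paste(
      allele_pair(g, hemizygous), collapse = " "))

  n <- length(triads$family_id)
  lines <- character(3L * n)
  for (i in seq_len(n)) {
    fid <- triads$family_id[i]
    male <- triads$child_sex[i] == "male"
    lines[3L * i - 2L] <- paste(fid, "fa", 0, 0, 1, 1,
      paste(allele_pair(triads$father[i, ], TRUE), collapse = " "))
    lines[3L * i - 1L] <- paste(fid, "mo", 0, 0, 2, 1,
      paste(allele_pair(triads$mother[i, ], FALSE), collapse = " "))
    lines[3L * i] <- paste(fid, "ch", "fa", "mo", if (male) 1 else 2, 2,
      paste(allele_pair(triads$child[i, ], male), collapse = " "))
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}
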