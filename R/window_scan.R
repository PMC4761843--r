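# Sliding-window orchestration: SNP filtering, per-window association and
# PHE tests, Bonferroni correction, plot data, and the genotype-dependent
# missingness diagnostic.

#' Scan configuration
#'
#' @param window_width SNPs per haplotype window (default 4).
#' @param maf_threshold parental minor-allele-frequency filter; SNPs are
#'   kept only if their parental MAF is strictly greater (default 0.05).
#' @param rare_threshold haplotype pooling threshold (default 0.01).
#' @param alpha family-wise level for the Bonferroni threshold (default
#'   0.05).
#' @param coding male dosage coding, `"double"` or `"single"`.
#' @param sex_subset `"both"`, `"boys"` or `"girls"`.
#' @return a validated `scan_config` list.
#' @export
scan_config <- function(window_width = 4L, maf_threshold = 0.05,
                        rare_threshold = 0.01, alpha = 0.05,
                        coding = c("double", "single"),
                        sex_subset = c("both", "boys", "girls")) {
  coding <- match.arg(coding); sex_subset <- match.arg(sex_subset)
  stopifnot(window_width >= 1L, maf_threshold > 0, maf_threshold < 0.5,
            rare_threshold >= 0, rare_threshold < 1, alpha > 0, alpha < 1)
  structure(list(window_width = as.integer(window_width),
                 maf_threshold = maf_threshold,
                 rare_threshold = rare_threshold, alpha = alpha,
                 coding = coding, sex_subset = sex_subset),
            class = "scan_config")
}

#' Parental minor-allele frequency per locus
#'
#' Fathers contribute one X allele, mothers two; missing calls are
#' excluded locus-wise.  The returned value is the frequency of the allele
#' coded 1, folded to the minor side (`min(f, 1 - f)`).
#'
#' @param triads a `triad_set`.
#' @return numeric vector, one MAF per locus.
#' @export
parental_maf <- function(triads) {
  fa <- triads$father; mo <- triads$mother
  num <- colSums(fa, na.rm = TRUE) + colSums(mo, na.rm = TRUE)
  den <- colSums(!is.na(fa)) + 2 * colSums(!is.na(mo))
  f <- num / den
  pmin(f, 1 - f)
}

#' Filter the SNP panel by parental MAF and an exclusion list
#'
#' @param triads a `triad_set`.
#' @param maf_threshold SNPs are retained only if parental MAF is strictly
#'   greater than this (a MAF of exactly the threshold is excluded).
#' @param exclude character vector of SNP ids to drop regardless of MAF.
#' @return a `triad_set` restricted to the retained panel, map order
#'   preserved.
#' @export
filter_snps <- function(triads, maf_threshold = 0.05, exclude = character(0)) {
  keep <- parental_maf(triads) > maf_threshold &
    !(triads$map$snp %in% exclude)
  if (!any(keep))
    pixhap_stop("no SNPs pass the parental MAF filter", "pixhap_empty_panel_error")
  subset_triads(triads, loci = which(keep))
}

#' Bonferroni-corrected per-window significance threshold
#'
#' With a sliding window of width w over S SNPs there are S - (w - 1)
#' haplotype tests, so the threshold is `alpha / (S - w + 1)`.
#'
#' @param n_snps SNPs in the filtered panel.
#' @param window_width window width.
#' @param alpha family-wise level.
#' @return the per-window threshold.
#' @export
bonferroni_threshold <- function(n_snps, window_width = 4L, alpha = 0.05) {
  n_windows <- n_snps - window_width + 1L
  stopifnot(n_windows >= 1L)
  alpha / n_windows
}

#' Sliding-window haplotype association and PHE scan
#'
#' For each window of `window_width` adjacent SNPs in panel order:
#' phase the triads (window-local exclusion of missing/Mendelian
#' families), estimate parental haplotype frequencies, pool rare
#' haplotypes, and run both the haplotype association LRT and the PHE
#' diagnostic LRT.  Degenerate windows are recorded and the scan
#' continues.
#'
#' @param triads a `triad_set`, already MAF-filtered (or pass
#'   `filter = TRUE` to filter here).
#' @param config a `scan_config`.
#' @param filter apply [filter_snps()] first (default `TRUE`).
#' @param exclude SNP ids to exclude when filtering.
#' @return a `pixhap_scan` data frame with one row per window: first-SNP
#'   id and position, family counts, df, chi-squared, p-values for the
#'   association and PHE tests, and status columns.  The Bonferroni
#'   threshold and the config are attached as attributes.
#' @export
pixhap_scan <- function(triads, config = scan_config(), filter = TRUE,
                        exclude = character(0)) {
  if (filter) triads <- filter_snps(triads, config$maf_threshold, exclude)
  L <- ncol(triads$father)
  w <- config$window_width
  if (L < w)
    pixhap_stop("fewer SNPs than the window width", "pixhap_empty_panel_error")
  n_windows <- L - w + 1L
  thr <- bonferroni_threshold(L, w, config$alpha)
  rows <- vector("list", n_windows)
  for (k in seq_len(n_windows)) {
    loci <- k:(k + w - 1L)
    win <- subset_triads(triads, loci = loci)
    ph <- phase_triads(win)
    row <- data.frame(
      window = k, snp = triads$map$snp[k], pos = triads$map$pos[k],
      n_phased = length(ph$family_id), n_informative = NA_integer_,
      n_common = NA_integer_, df = NA_integer_, chi2 = NA_real_,
      p = NA_real_, phe_chi2 = NA_real_, phe_p = NA_real_,
      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      cb <- build_codebook(ph, threshold = config$rare_threshold,
                           window_id = paste0("w", k))
      lrt <- pixhap_lrt(ph, cb, coding = config$coding,
                        sex_subset = config$sex_subset)
      phe <- phe_lrt(ph, cb)
      row$n_informative <- lrt$n_informative
      row$n_common <- length(cb$common)
      row$df <- lrt$df; row$chi2 <- lrt$chi2; row$p <- lrt$p_value
      row$phe_chi2 <- phe$chi2; row$phe_p <- phe$p_value
      row$status <- if (lrt$status != "ok") lrt$status else phe$status
      row
    }, pixhap_degenerate_window_error = function(e) {
      row$status <- "degenerate"; row
    })
    rows[[k]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "config") <- config
  class(out) <- c("pixhap_scan", "data.frame")
  out
}

#' Write scan results as a tab-separated table
#'
#' @param scan a `pixhap_scan` data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Manhattan-plot data: position vs -log10(p)
#'
#' @param scan a `pixhap_scan`.
#' @param test `"association"` or `"phe"`.
#' @return data frame with `pos`, `neg_log10_p` and the threshold line.
#' @export
manhattan_data <- function(scan, test = c("association", "phe")) {
  test <- match.arg(test)
  p <- if (test == "association") scan$p else scan$phe_p
  data.frame(window = scan$window, snp = scan$snp, pos = scan$pos,
             neg_log10_p = -log10(p),
             threshold = -log10(attr(scan, "bonferroni_threshold")))
}

#' QQ-plot data against uniform order statistics
#'
#' Expected quantiles are `-log10((i - 0.5) / n)` for the i-th smallest
#' p-value.
#'
#' @param p numeric vector of p-values (`NA` dropped).
#' @return data frame with `expected` and `observed` columns, sorted.
#' @export
qq_data <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}

#' Manhattan plot of a scan
#'
#' @inheritParams manhattan_data
#' @return a ggplot object (requires ggplot2).
#' @export
plot_manhattan <- function(scan, test = c("association", "phe")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    pixhap_stop("ggplot2 is required for plotting", "pixhap_config_error")
  d <- manhattan_data(scan, test)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$neg_log10_p)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = d$threshold[1], linetype = "dashed") +
    ggplot2::labs(x = "position of first SNP in window",
                  y = expression(-log[10](p)))
}

#' QQ plot of scan p-values
#'
#' @param p p-value vector.
#' @return a ggplot object (requires ggplot2).
#' @export
plot_qq <- function(p) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    pixhap_stop("ggplot2 is required for plotting", "pixhap_config_error")
  d <- qq_data(p)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)))
}

#' Genotype-dependent missingness diagnostic
#'
#' Cross-tabulates, separately for fathers, mothers, sons and daughters,
#' the genotype at one locus against called/missing status at another.
#' Call failure at a locus that depends on the genotype at a nearby locus
#' makes haplotypes informatively missing and can fabricate association
#' signals, so carrier status at `locus_a` is tested against missingness
#' at `locus_b` with a two-sided Fisher exact test per role.
#'
#' @param triads a `triad_set` with missing calls retained (`NA`).
#' @param locus_a,locus_b locus indices or SNP ids.
#' @param flag_level significance level for the `flagged` indicator
#'   (default 0.05; Bonferroni-adjust externally when screening many
#'   pairs).
#' @return a list per role with the genotype x called/missing table and
#'   the Fisher p-value, plus `p_pooled` across roles and `flagged`.
#'   The flag Bonferroni-combines the four per-role tests (missingness is
#'   often role-specific, and pooling roles confounds carrier rates that
#'   differ between hemizygous and diploid carriers).
#' @export
missingness_crosstab <- function(triads, locus_a, locus_b, flag_level = 0.05) {
  ia <- locus_index(triads, locus_a); ib <- locus_index(triads, locus_b)
  male <- triads$child_sex == "male"
  roles <- list(
    father = triads$father,
    mother = triads$mother,
    son = triads$child[male, , drop = FALSE],
    daughter = triads$child[!male, , drop = FALSE])
  out <- lapply(roles, function(g) {
    ga <- g[, ia]; miss_b <- is.na(g[, ib])
    tab <- table(genotype_a = factor(ga, levels = 0:2),
                 locus_b = factor(ifelse(miss_b, "missing", "called"),
                                  levels = c("called", "missing")))
    carrier <- factor(ifelse(ga > 0, "carrier", "noncarrier"),
                      levels = c("noncarrier", "carrier"))
    ct <- table(carrier, miss_b = factor(miss_b, levels = c(FALSE, TRUE)))
    p <- if (all(dim(ct) == c(2L, 2L)) && sum(ct) > 0L)
      stats::fisher.test(ct)$p.value else 1
    list(table = tab, p_value = p)
  })
  # pooled across roles: carriers vs noncarriers, called vs missing
  ga_all <- c(triads$father[, ia], triads$mother[, ia], triads$child[, ia])
  mb_all <- is.na(c(triads$father[, ib], triads$mother[, ib],
                    triads$child[, ib]))
  ok <- !is.na(ga_all)
  ct <- table(carrier = ga_all[ok] > 0,
              missing = factor(mb_all[ok], levels = c(FALSE, TRUE)))
  p_pooled <- if (nrow(ct) == 2L) stats::fisher.test(ct)$p.value else 1
  p_roles <- vapply(out, function(r) r$p_value, 0)
  c(out, list(p_pooled = p_pooled,
              flagged = min(p_roles) * length(p_roles) < flag_level))
}

locus_index <- function(triads, locus) {
  if (is.character(locus)) {
    i <- match(locus, triads$map$snp)
    if (is.na(i)) pixhap_stop(sprintf("SNP %s not in map", locus),
                              "pixhap_format_error")
    i
  } else as.integer(locus)
}
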