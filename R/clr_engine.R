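# Conditional-logistic engine: rare-haplotype pooling, exact conditional
# likelihood over 3-alternative strata, Newton-Raphson fitting, and the
# haplotype likelihood-ratio test.
#
# Model columns: one log-relative-risk coefficient per common (nonrare)
# haplotype except a reference, plus one nuisance coefficient for the
# pooled rare group.  Within a stratum the total haplotype count is
# constant, so the model is identified only relative to the reference;
# test p-values are invariant to which common haplotype is the reference.

#' Build the haplotype codebook for a window
#'
#' Parental haplotype frequencies are estimated by counting all three
#' parental haplotypes (one paternal, two maternal) with equal weight over
#' every family that passed phasing.  Haplotypes with frequency below
#' `threshold` are pooled into a single rare group; the most frequent
#' common haplotype is the reference.
#'
#' @param phased a `phased_triads` object.
#' @param threshold parental-frequency threshold for pooling (default
#'   0.01).
#' @param window_id identifier carried through to results.
#' @param reference optional label ("1100" style) of the common haplotype
#'   to use as the reference; default is the most frequent.  Test
#'   p-values are invariant to this choice.
#' @return an object of class `hap_codebook` with elements `common`,
#'   `rare` (integer codes), `frequencies` (named over observed
#'   haplotypes, summing to 1), `reference`, `col_of` (code -> model
#'   column, 0 for the reference), `columns` (column labels), `w`,
#'   `threshold`.
#' @export
build_codebook <- function(phased, threshold = 0.01, window_id = "w1",
                           reference = NULL) {
  stopifnot(threshold >= 0, threshold < 1)
  codes <- phased_codes(phased)
  if (nrow(codes) == 0L)
    pixhap_stop("no families passed phasing", "pixhap_degenerate_window_error")
  w <- ncol(phased$paternal)
  counts <- tabulate(codes, nbins = 2^w)
  freq <- counts / sum(counts)
  observed <- which(counts > 0L)
  common <- observed[freq[observed] >= threshold]
  rare <- observed[freq[observed] < threshold]
  if (length(common) < 2L)
    pixhap_stop(sprintf(
      "window %s: fewer than 2 common haplotypes; test undefined", window_id),
      "pixhap_degenerate_window_error")
  if (is.null(reference)) {
    reference <- common[which.max(freq[common])]
  } else {
    reference <- hap_parse(reference)
    if (!reference %in% common)
      pixhap_stop("reference must be a common haplotype",
                  "pixhap_config_error")
  }
  non_ref <- setdiff(common, reference)

  col_of <- rep(NA_integer_, 2^w)
  col_of[reference] <- 0L
  col_of[non_ref] <- seq_along(non_ref)
  columns <- hap_label(non_ref, w)
  if (length(rare) > 0L) {
    col_of[rare] <- length(non_ref) + 1L
    columns <- c(columns, "rare")
  }
  frequencies <- stats::setNames(freq[observed], hap_label(observed, w))
  structure(
    list(window_id = window_id, w = w, threshold = threshold,
         common = common, rare = rare, reference = reference,
         frequencies = frequencies, col_of = col_of, columns = columns,
         n_families = nrow(codes)),
    class = "hap_codebook")
}

#' @export
print.hap_codebook <- function(x, ...) {
  cat(sprintf(
    "hap_codebook %s: %d common + %d rare haplotypes from %d families; reference %s\n",
    x$window_id, length(x$common), length(x$rare), x$n_families,
    hap_label(x$reference, x$w)))
  invisible(x)
}

#' Dosage vector of one risk-set alternative
#'
#' Maps a haplotype multiset to model-column copy counts.  Females
#' contribute the count of each haplotype among their two copies; a male's
#' single haplotype counts as 2 under `"double"` coding (his risk equals a
#' homozygous female's) or 1 under `"single"`.
#'
#' @param haplotypes matrix of 0/1 indicator rows (1 row for a male, 2 for
#'   a female alternative).
#' @param child_sex `"male"` or `"female"`.
#' @param codebook a `hap_codebook`.
#' @param coding `"double"` or `"single"` male dosage coding.
#' @return named numeric vector over the model columns.
#' @export
hap_dosage <- function(haplotypes, child_sex, codebook,
                       coding = c("double", "single")) {
  coding <- match.arg(coding)
  codes <- hap_encode(haplotypes)
  p <- length(codebook$columns)
  out <- stats::setNames(numeric(p), codebook$columns)
  wgt <- if (child_sex == "male" && coding == "double") 2 else 1
  for (cd in codes) {
    cl <- codebook$col_of[cd]
    if (is.na(cl))
      pixhap_stop("haplotype not present in codebook", "pixhap_dimension_error")
    if (cl > 0L) out[cl] <- out[cl] + wgt
  }
  out
}

# Dense dosage array for vectorized fitting.
#
# ra: result of risk_alternatives(); returns X (3n x p, stratum-major with
# the case row first in each stratum) plus bookkeeping.  male_weight is 2
# ("double") or 1 ("single"); PHE risk sets pass single-haplotype
# alternatives with weight 1.
dosage_matrix <- function(ra, codebook, male_weight = 2) {
  n <- ra$n
  p <- length(codebook$columns)
  nalt <- length(ra$alts)
  X <- matrix(0, n * nalt, p, dimnames = list(NULL, codebook$columns))
  for (j in seq_len(nalt)) {
    rows <- (seq_len(n) - 1L) * nalt + j
    cm <- ra$alts[[j]]
    for (slot in 1:2) {
      cds <- cm[, slot]
      ok <- !is.na(cds)
      if (!any(ok)) next
      cl <- codebook$col_of[cds[ok]]
      wgt <- rep(1, sum(ok))
      if (slot == 1L) wgt[ra$male[ok]] <- male_weight
      hit <- !is.na(cl) & cl > 0L
      if (any(hit)) {
        idx <- cbind(rows[ok][hit], cl[hit])
        X[idx] <- X[idx] + wgt[hit]
      }
    }
  }
  list(X = X, n = n, nalt = nalt)
}

#' Exact conditional log-likelihood
#'
#' Sum over strata of `eta_case - log(sum_j exp(eta_j))` where
#' `eta = dosage . beta`.  Exact: every stratum enumerates its 3 (or 2)
#' alternatives.
#'
#' @param risk_sets a list of `risk_set` objects.
#' @param beta named coefficient vector over the codebook's model columns.
#' @param codebook a `hap_codebook`.
#' @param coding male dosage coding.
#' @return the conditional log-likelihood (a scalar, always <= 0).
#' @export
conditional_log_likelihood <- function(risk_sets, beta, codebook,
                                       coding = c("double", "single")) {
  coding <- match.arg(coding)
  p <- length(codebook$columns)
  if (length(beta) != p)
    pixhap_stop(sprintf("beta has length %d, model has %d columns",
                        length(beta), p), "pixhap_dimension_error")
  ll <- 0
  for (rs in risk_sets) {
    eta <- vapply(rs$alternatives, function(a)
      sum(hap_dosage(a, rs$child_sex, codebook, coding) * beta), 0)
    m <- max(eta)
    ll <- ll + eta[rs$case_index] - m - log(sum(exp(eta - m)))
  }
  ll
}

# Newton-Raphson maximizer of the stratified conditional likelihood.
#
# X: dosage matrix from dosage_matrix() (case row first per stratum).
# Columns with no within-stratum variation contribute a constant to every
# stratum's linear predictor, cancel from the conditional likelihood, and
# are structurally inestimable; they are dropped (coefficient NA) and the
# fit flagged degenerate.
fit_clr_matrix <- function(X, n, nalt, max_iter = 50L, score_tol = 1e-8,
                           step_tol = 1e-10) {
  p <- ncol(X)
  grp <- rep(seq_len(n), each = nalt)
  estimable <- rep(TRUE, p)
  if (p > 0L) {
    A <- rowsum(X, grp) / nalt
    D <- X - A[grp, , drop = FALSE]
    estimable <- colSums(abs(D)) > 1e-12
  }
  Xe <- X[, estimable, drop = FALSE]
  pe <- ncol(Xe)
  beta <- numeric(pe)
  case_rows <- (seq_len(n) - 1L) * nalt + 1L

  loglik_at <- function(b) {
    eta <- matrix(if (pe > 0L) as.vector(Xe %*% b) else 0,
                  nrow = nalt, ncol = n)
    m <- apply(eta, 2L, max)
    lse <- m + log(colSums(exp(sweep(eta, 2L, m))))
    list(ll = sum(eta[1L, ] - lse),
         w = exp(sweep(eta, 2L, lse)))   # nalt x n alternative probabilities
  }

  if (pe == 0L) {
    return(list(coef = rep(NA_real_, p), loglik = -n * log(nalt),
                converged = TRUE, iterations = 0L, n_strata = n,
                estimable = estimable, separation = FALSE))
  }

  cur <- loglik_at(beta)
  converged <- FALSE
  iter <- 0L
  y <- numeric(n * nalt); y[case_rows] <- 1
  repeat {
    iter <- iter + 1L
    wv <- as.vector(cur$w)                      # stratum-major, alt fastest
    score <- crossprod(Xe, y - wv)
    if (max(abs(score)) < score_tol) { converged <- TRUE; break }
    M <- rowsum(wv * Xe, grp)                   # n x pe weighted means
    H <- crossprod(Xe, wv * Xe) - crossprod(M)
    delta <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(delta))
      delta <- solve(H + diag(1e-8, pe), score)
    # step-halving on likelihood decrease
    step <- 1
    repeat {
      cand <- beta + step * as.vector(delta)
      new <- loglik_at(cand)
      if (new$ll >= cur$ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    moved <- max(abs(cand - beta))
    beta <- cand; cur <- new
    if (moved < step_tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  separation <- any(abs(beta) > 10)
  coef <- rep(NA_real_, p)
  coef[estimable] <- beta
  list(coef = coef, loglik = cur$ll, converged = converged,
       iterations = iter, n_strata = n, estimable = estimable,
       separation = separation)
}

#' Fit the conditional-logistic model for a window
#'
#' @param phased a `phased_triads` object (noninformative families are
#'   excluded internally).
#' @param codebook a `hap_codebook` built from the same phased window.
#' @param coding male dosage coding, `"double"` (default) or `"single"`.
#' @param model `"alternative"` (a coefficient per nonreference common
#'   haplotype plus the rare group) or `"null"` (rare-group coefficient
#'   only).
#' @param sex_subset restrict strata to `"boys"`, `"girls"`, or use
#'   `"both"` (default).
#' @return a `clr_fit`: `coefficients` (named; `NA` for structurally
#'   inestimable columns), `log_likelihood`, `converged`, `n_strata`,
#'   `iterations`, `separation`.
#' @export
fit_clr <- function(phased, codebook, coding = c("double", "single"),
                    model = c("alternative", "null"),
                    sex_subset = c("both", "boys", "girls")) {
  coding <- match.arg(coding); model <- match.arg(model)
  sex_subset <- match.arg(sex_subset)
  ra <- risk_alternatives(phased)
  ra <- subset_alternatives(ra, sex_subset)
  if (ra$n == 0L)
    pixhap_stop("no informative strata", "pixhap_degenerate_window_error")
  dm <- dosage_matrix(ra, codebook, male_weight = if (coding == "double") 2 else 1)
  X <- dm$X
  if (model == "null") {
    keep <- colnames(X) == "rare"
    X <- X[, keep, drop = FALSE]
  }
  fit <- fit_clr_matrix(X, dm$n, dm$nalt)
  structure(
    list(coefficients = stats::setNames(fit$coef, colnames(X)),
         log_likelihood = fit$loglik, converged = fit$converged,
         n_strata = fit$n_strata, iterations = fit$iterations,
         separation = fit$separation,
         degenerate_columns = colnames(X)[!fit$estimable],
         model = model, coding = coding),
    class = "clr_fit")
}

subset_alternatives <- function(ra, sex_subset) {
  if (sex_subset == "both") return(ra)
  keep <- if (sex_subset == "boys") ra$male else !ra$male
  ra$alts <- lapply(ra$alts, function(a) a[keep, , drop = FALSE])
  ra$male <- ra$male[keep]
  ra$family_id <- ra$family_id[keep]
  ra$n <- sum(keep)
  ra
}

#' @export
print.clr_fit <- function(x, ...) {
  cat(sprintf("clr_fit (%s model, %s coding): %d strata, loglik %.4f, %s in %d iterations\n",
              x$model, x$coding, x$n_strata, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Haplotype likelihood-ratio test for one window
#'
#' Twice the gap between the alternative conditional log-likelihood (a
#' coefficient per nonreference common haplotype plus the pooled rare
#' group) and the null (rare-group coefficient only), referred to a
#' chi-squared with (number of common haplotypes - 1) degrees of freedom.
#'
#' @inheritParams fit_clr
#' @return an `lrt_result` with `chi2`, `df`, `p_value`, `fit_alt`,
#'   `fit_null`, `n_informative`, `status` (`"ok"`, `"degenerate"`, or
#'   `"nonconverged"`).
#' @export
pixhap_lrt <- function(phased, codebook, coding = c("double", "single"),
                       sex_subset = c("both", "boys", "girls")) {
  coding <- match.arg(coding); sex_subset <- match.arg(sex_subset)
  fit_alt <- fit_clr(phased, codebook, coding, "alternative", sex_subset)
  fit_null <- fit_clr(phased, codebook, coding, "null", sex_subset)
  lrt_from_fits(fit_alt, fit_null, df = length(codebook$common) - 1L,
                window_id = codebook$window_id)
}

lrt_from_fits <- function(fit_alt, fit_null, df, window_id) {
  chi2 <- 2 * (fit_alt$log_likelihood - fit_null$log_likelihood)
  if (chi2 < 0 && chi2 > -1e-6) chi2 <- 0
  status <- if (!fit_alt$converged || !fit_null$converged) "nonconverged"
  else if (length(fit_alt$degenerate_columns) > 0L ||
           length(fit_null$degenerate_columns) > 0L) "degenerate"
  else "ok"
  structure(
    list(window_id = window_id, chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         fit_alt = fit_alt, fit_null = fit_null,
         n_informative = fit_alt$n_strata, status = status),
    class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s: chi2 = %.3f on %d df, p = %.3g (%d informative families, status %s)\n",
              x$window_id, x$chi2, x$df, x$p_value, x$n_informative, x$status))
  invisible(x)
}

#' Relative-risk estimates from a window fit
#'
#' @param lrt an `lrt_result`.
#' @return data frame of per-column log relative risks and `exp(beta)`;
#'   under `"double"` coding `exp(2 beta)` is the boys' relative risk.
#' @export
hap_relative_risks <- function(lrt) {
  b <- lrt$fit_alt$coefficients
  data.frame(haplotype = names(b), beta = unname(b), rr = exp(unname(b)),
             rr_male_double = exp(2 * unname(b)), row.names = NULL)
}
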