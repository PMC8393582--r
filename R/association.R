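#' Chi-square allele-frequency contrast between bulks
#'
#' Pearson chi-square test (1 df, no continuity correction) on a 2x2
#' contingency table of allele depths: bulks (high-EBV, low-EBV) by
#' alleles (ref, alt).  A locus that is monomorphic across both bulks
#' (a zero allele column) is not testable and returns `NA` statistics.
#'
#' @param m_H,p_H alternative- and reference-allele depths in the
#'   high-EBV bulk (vectorised).
#' @param m_L,p_L the same for the low-EBV bulk.
#' @return data frame with columns `chi2`, `p_raw` and `testable`.
#' @export
chi_square_bulk_test <- function(m_H, p_H, m_L, p_L) {
  n <- length(m_H)
  stopifnot(length(p_H) == n, length(m_L) == n, length(p_L) == n)
  if (any(c(m_H, p_H, m_L, p_L) < 0, na.rm = TRUE)) {
    stop("allele depths must be non-negative", call. = FALSE)
  }
  row_H <- m_H + p_H
  row_L <- m_L + p_L
  if (any(is.na(row_H + row_L)) || any(row_H == 0) || any(row_L == 0)) {
    stop("both bulks need positive allele depth at every locus",
         call. = FALSE)
  }
  col_m <- m_H + m_L
  col_p <- p_H + p_L
  testable <- col_m > 0 & col_p > 0
  total <- row_H + row_L
  # closed form for the 2x2 Pearson statistic: N (ad - bc)^2 / (r1 r2 c1 c2)
  chi2 <- ifelse(testable,
                 total * (m_H * p_L - p_H * m_L)^2 /
                   (row_H * row_L * col_m * col_p),
                 NA_real_)
  p_raw <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chi2 = chi2, p_raw = p_raw, testable = testable)
}

#' Multiple-testing adjustment of p-values
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg false discovery
#' rate step-up with monotonicity enforcement, via [stats::p.adjust()].
#' Output order matches input order; `NA` entries (untestable loci)
#' propagate and do not count towards `m`.
#'
#' @param p_raw numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @param method `"fdr"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @return adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p_raw, method = c("fdr", "bonferroni")) {
  method <- match.arg(method)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = if (method == "fdr") "BH" else "bonferroni")
}

#' Run the bulk association screen over a scored locus table
#'
#' Applies [chi_square_bulk_test()] to every locus of a scored table
#' (typically the [filter_loci()] survivors), attaches FDR and Bonferroni
#' adjusted p-values and a deterministic rank (by raw p, ties broken by
#' locus id).
#'
#' @param scored a scored locus table with `m_H`, `p_H`, `m_L`, `p_L`
#'   columns (see [score_loci()]).
#' @return the input with appended `chi2`, `p_raw`, `p_fdr`, `p_bonf`
#'   and `rank` columns, input order preserved.
#' @export
test_bulk_loci <- function(scored) {
  if (nrow(scored) == 0) {
    out <- scored
    out$chi2 <- out$p_raw <- out$p_fdr <- out$p_bonf <- numeric(0)
    out$rank <- integer(0)
    return(out)
  }
  res <- chi_square_bulk_test(scored$m_H, scored$p_H,
                              scored$m_L, scored$p_L)
  out <- scored
  out$chi2 <- res$chi2
  out$p_raw <- res$p_raw
  out$p_fdr <- adjust_pvalues(res$p_raw, "fdr")
  out$p_bonf <- adjust_pvalues(res$p_raw, "bonferroni")
  ord <- order(out$p_raw, out$locus_id, na.last = TRUE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Staged candidate selection from an association screen
#'
#' Implements the two staged selection rules of the screen: loci whose
#' Bonferroni-adjusted p-value clears the family-wise level, or the `k`
#' loci with the smallest raw p-values (the "highest significant"
#' shortlist carried into individual genotyping).
#'
#' @param results an association table from [test_bulk_loci()] with
#'   `locus_id`, `p_raw` and `p_bonf` columns.
#' @param stage `"bonferroni_hits"` or `"top_k"`.
#' @param k shortlist size for `stage = "top_k"`.
#' @param alpha family-wise error level for `stage = "bonferroni_hits"`.
#' @return character vector of selected locus ids, ordered by
#'   `(p_raw, locus_id)`.
#' @export
select_candidates <- function(results, stage = c("bonferroni_hits", "top_k"),
                              k = 31, alpha = 0.05) {
  stage <- match.arg(stage)
  testable <- results[!is.na(results$p_raw), , drop = FALSE]
  testable <- testable[order(testable$p_raw, testable$locus_id), ,
                       drop = FALSE]
  if (stage == "bonferroni_hits") {
    return(testable$locus_id[testable$p_bonf < alpha])
  }
  k <- check_count(k, "k")
  if (k > nrow(testable)) {
    warning(sprintf("k = %d exceeds the %d testable loci; truncating",
                    k, nrow(testable)))
    k <- nrow(testable)
  }
  testable$locus_id[seq_len(k)]
}
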