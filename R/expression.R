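#' Relative expression by the 2^-ddCT method
#'
#' For each biological sample, technical replicates are averaged and
#' `dCT = mean(ct_target) - mean(ct_reference)`; `ddCT` is the sample's
#' `dCT` minus the mean `dCT` of the calibrator genotype group; relative
#' quantity is `RQ = 2^-ddCT`.  By construction the calibrator group's
#' geometric mean RQ is 1.
#'
#' @param ct a CT data frame (see [simulate_expression()]) with columns
#'   `sample_id`, `genotype_group`, `ct_target`, `ct_reference` (and
#'   optionally `gene`, `replicate`).
#' @param calibrator calibrator group label; defaults to the first group
#'   level in the table (conventionally the reference-homozygote group).
#' @return data frame with one row per sample: `sample_id`,
#'   `genotype_group`, `dct`, `ddct`, `rq`.  Samples with missing
#'   reference CT are dropped with a warning.
#' @export
relative_quantity <- function(ct, calibrator = NULL) {
  required <- c("sample_id", "genotype_group", "ct_target", "ct_reference")
  stopifnot(all(required %in% names(ct)))
  bad <- !is.finite(ct$ct_target) | !is.finite(ct$ct_reference)
  if (any(bad)) {
    warning(sum(bad), " well(s) with missing CT dropped")
    ct <- ct[!bad, , drop = FALSE]
  }
  if (nrow(ct) == 0) stop("no usable CT records", call. = FALSE)

  agg <- stats::aggregate(
    cbind(ct_target, ct_reference) ~ sample_id + genotype_group,
    data = ct, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference

  calibrator <- calibrator %||% ct$genotype_group[1]
  cal <- agg$genotype_group == calibrator
  if (!any(cal)) {
    stop("calibrator group not present: ", calibrator, call. = FALSE)
  }
  agg$ddct <- agg$dct - mean(agg$dct[cal])
  agg$rq <- 2^(-agg$ddct)
  out <- agg[order(agg$genotype_group, agg$sample_id),
             c("sample_id", "genotype_group", "dct", "ddct", "rq")]
  rownames(out) <- NULL
  out
}

#' Compare relative expression between genotype groups
#'
#' Two-tailed two-sample t-test of relative quantities between two
#' genotype groups.  By default the test is run on `log2(RQ)` (equal to
#' `-ddCT`), since RQ is log-normal when CT noise is Gaussian; set
#' `scale = "rq"` to test raw RQ values.
#'
#' @param rq a per-sample RQ table from [relative_quantity()].
#' @param groups the two group labels to compare; defaults to the first
#'   two groups in the table (first = reference).
#' @param scale `"log2"` (default) or `"rq"`.
#' @return list with `t`, `p`, `direction` (`"up"`/`"down"`/`"none"`:
#'   sign of the alternative group's mean expression relative to the
#'   reference group), and the per-group mean and SE of RQ.
#' @export
compare_groups <- function(rq, groups = NULL, scale = c("log2", "rq")) {
  scale <- match.arg(scale)
  groups <- groups %||% unique(rq$genotype_group)[1:2]
  stopifnot(length(groups) == 2)
  a <- rq$rq[rq$genotype_group == groups[1]]
  b <- rq$rq[rq$genotype_group == groups[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  xa <- if (scale == "log2") log2(a) else a
  xb <- if (scale == "log2") log2(b) else b
  tt <- stats::t.test(xb, xa, alternative = "two.sided")
  diff <- mean(xb) - mean(xa)
  list(
    t = unname(tt$statistic), p = tt$p.value,
    direction = if (diff > 0) "up" else if (diff < 0) "down" else "none",
    group_stats = data.frame(
      genotype_group = groups,
      n = c(length(a), length(b)),
      mean_rq = c(mean(a), mean(b)),
      se_rq = c(stats::sd(a) / sqrt(length(a)),
                stats::sd(b) / sqrt(length(b))),
      stringsAsFactors = FALSE
    )
  )
}
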