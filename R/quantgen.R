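#' Shapiro-Wilk normality check for a trait vector
#'
#' Thin wrapper over [stats::shapiro.test()] with explicit degenerate-input
#' handling, used to check marketing weight for normality before any
#' association analysis.
#'
#' @param values numeric trait vector (`NA` dropped); between 3 and 5000
#'   non-missing values.
#' @return list with `W` and `p`.
#' @export
check_normality <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(x) > 5000) stop("Shapiro-Wilk is defined for n <= 5000",
                             call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("trait is constant: normality test undefined", call. = FALSE)
  }
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Estimate variance components from a nested sib design
#'
#' Fits the random-intercept model `trait ~ (1 | sire) + (1 | sire:dam)`
#' with [lme4::lmer()] (plus a fixed sex effect when more than one sex is
#' present) and converts the between-family variance to additive genetic
#' variance through the standard half-sib covariance: the sire component
#' estimates a quarter of `sigma2_A`.  The dam-within-sire component is
#' not used for `sigma2_A` because full-sib covariance is contaminated by
#' dominance and common environment.
#'
#' Two definitions of within-family heritability `h2_w` (the shrinkage
#' applied to an individual's within-family deviation when predicting its
#' breeding value) are offered: `"residual"` is `0.5 * sigma2_A /
#' sigma2_e` with `sigma2_e` the model residual variance; `"phenotypic"`
#' is the textbook `0.5 * sigma2_A / sigma2_P`.
#'
#' @param individuals data frame with `id`, `sire_id`, `dam_id`, `mw`
#'   columns (and optionally `sex`); rows without phenotype or parent
#'   links are ignored for fitting.
#' @param h2w_definition denominator convention for `h2_w` (see above).
#' @return an object of class `variance_components`: a list with
#'   `sigma2_A`, `sigma2_e`, `sigma2_P`, `h2` (clipped to `[0, 1]`),
#'   `h2_w`, the component table, and the fitted model (used by
#'   [estimate_ebv()]).
#' @export
estimate_variance_components <- function(individuals,
                                         h2w_definition = c("residual",
                                                            "phenotypic")) {
  h2w_definition <- match.arg(h2w_definition)
  d <- individuals[!is.na(individuals$mw) & !is.na(individuals$sire_id) &
                     !is.na(individuals$dam_id), , drop = FALSE]
  if (length(unique(d$sire_id)) < 2) {
    stop("need at least 2 sire families to separate variance components",
         call. = FALSE)
  }
  use_sex <- "sex" %in% names(d) && length(unique(d$sex)) > 1
  form <- if (use_sex) {
    mw ~ sex + (1 | sire_id) + (1 | sire_id:dam_id)
  } else {
    mw ~ 1 + (1 | sire_id) + (1 | sire_id:dam_id)
  }
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  sigma2_sire <- get_vc("sire_id")
  sigma2_dam <- get_vc("sire_id:dam_id")
  sigma2_res <- get_vc("Residual")
  sigma2_A <- 4 * sigma2_sire
  sigma2_P <- sigma2_sire + sigma2_dam + sigma2_res
  h2 <- min(1, max(0, sigma2_A / sigma2_P))
  denom <- if (h2w_definition == "residual") sigma2_res else sigma2_P
  h2_w <- if (denom > 0) 0.5 * sigma2_A / denom else 0
  structure(list(
    sigma2_A = sigma2_A, sigma2_e = sigma2_res, sigma2_P = sigma2_P,
    sigma2_sire = sigma2_sire, sigma2_dam = sigma2_dam,
    h2 = h2, h2_w = h2_w, h2w_definition = h2w_definition,
    model = fit, data = d
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Nested sib variance components\n")
  cat(sprintf("  sigma2_A = %.4f  sigma2_e = %.4f  sigma2_P = %.4f\n",
              x$sigma2_A, x$sigma2_e, x$sigma2_P))
  cat(sprintf("  h2 = %.3f   h2_w (%s) = %.3f\n",
              x$h2, x$h2w_definition, x$h2_w))
  invisible(x)
}

#' Predict estimated breeding values from sib information
#'
#' Predicts each phenotyped individual's breeding value as the
#' parent-average plus a shrunken within-family deviation:
#' `EBV = 1/2 (a_sire + a_dam) + h2_w * e`, where the parental breeding
#' values are twice the sire and dam-within-sire BLUPs of the fitted
#' family model (so their average is exactly the model's random-effect
#' contribution) and `e` is the individual's model residual.  Individuals
#' absent from the fitted model (missing parent links) are treated as
#' founders with parent-average 0, shrinking their deviation from the
#' fixed-effect prediction instead.
#'
#' @param individuals data frame with `id`, `sire_id`, `dam_id`, `mw`
#'   (and `sex` if the model used it).
#' @param vc a `variance_components` object from
#'   [estimate_variance_components()].
#' @return data frame `id`, `ebv` (kg) for every phenotyped individual,
#'   in input order.
#' @export
estimate_ebv <- function(individuals, vc) {
  stopifnot(inherits(vc, "variance_components"))
  d <- individuals[!is.na(individuals$mw), , drop = FALSE]
  in_model <- !is.na(d$sire_id) & !is.na(d$dam_id) &
    d$id %in% vc$data$id
  ebv <- numeric(nrow(d))

  if (any(in_model)) {
    md <- vc$data
    fixed <- stats::predict(vc$model, newdata = md, re.form = NA)
    fam <- stats::fitted(vc$model) - fixed      # u_sire + u_dam per row
    res <- stats::residuals(vc$model)
    idx <- match(d$id[in_model], md$id)
    ebv[in_model] <- fam[idx] + vc$h2_w * res[idx]
  }
  if (any(!in_model)) {
    nd <- d[!in_model, , drop = FALSE]
    fixed <- stats::predict(vc$model, newdata = nd, re.form = NA,
                            allow.new.levels = TRUE)
    ebv[!in_model] <- vc$h2_w * (nd$mw - fixed)
  }
  data.frame(id = d$id, ebv = ebv, stringsAsFactors = FALSE)
}

#' Select the extreme low- and high-EBV groups
#'
#' Returns the ids of the `n_per_tail` lowest- and highest-ranked
#' individuals by estimated breeding value, the sampling rule used to
#' build the two DNA bulks.  Ties are broken by id for determinism.
#'
#' @param ebvs data frame with `id` and `ebv` columns (as returned by
#'   [estimate_ebv()]), or a named numeric vector.
#' @param n_per_tail individuals per tail; at most half the total.
#' @return list with character vectors `low` and `high`.
#' @export
select_extreme_groups <- function(ebvs, n_per_tail = 20) {
  if (is.numeric(ebvs) && !is.null(names(ebvs))) {
    ebvs <- data.frame(id = names(ebvs), ebv = unname(ebvs),
                       stringsAsFactors = FALSE)
  }
  n_per_tail <- check_count(n_per_tail, "n_per_tail")
  if (n_per_tail > nrow(ebvs) / 2) {
    stop("`n_per_tail` must not exceed half the number of individuals",
         call. = FALSE)
  }
  ord <- order(ebvs$ebv, ebvs$id)
  list(low = ebvs$id[ord[seq_len(n_per_tail)]],
       high = ebvs$id[rev(ord)[seq_len(n_per_tail)]])
}

#' Allele and genotype frequencies at one locus
#'
#' Genotype frequencies over called individuals and allele frequencies by
#' gene counting.
#'
#' @param genotypes character vector of unordered allele pairs, either
#'   `"A/G"` or `"AG"` style; `NA` for missing calls.
#' @return list with named numeric vectors `allele_freqs` and
#'   `genotype_freqs` (genotype labels normalised to sorted `"X/Y"`).
#' @export
compute_frequencies <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) stop("no called genotypes", call. = FALSE)
  pairs <- lapply(g, function(s) {
    al <- if (grepl("/", s, fixed = TRUE)) {
      strsplit(s, "/", fixed = TRUE)[[1]]
    } else {
      strsplit(s, "")[[1]]
    }
    if (length(al) != 2) stop("genotype must be an allele pair: ", s,
                              call. = FALSE)
    sort(al)
  })
  labels <- vapply(pairs, paste, character(1), collapse = "/")
  geno_tab <- table(labels)
  alleles <- unlist(pairs)
  allele_tab <- table(alleles)
  list(
    allele_freqs = stats::setNames(as.numeric(allele_tab) / length(alleles),
                                   names(allele_tab)),
    genotype_freqs = stats::setNames(as.numeric(geno_tab) / length(g),
                                     names(geno_tab))
  )
}

#' Additive, dominance and recessive effect decomposition at one locus
#'
#' Three separate single-predictor linear regressions of the trait on
#' alternative-allele codings across \{ref-hom, het, alt-hom\}: additive
#' `(0, 1, 2)` (effect per allele copy), dominance `(0, 1, 1)` and
#' recessive `(0, 0, 1)`.  Each fit reports the slope (kg), its standard
#' error, p-value and the constant-free [aic_rss()] of the model; a
#' coding that is constant in the data (e.g. recessive with no
#' alt-homozygotes) is flagged inestimable.
#'
#' @param geno_count integer vector of alternative-allele counts
#'   (0, 1, 2); `NA` dropped.
#' @param mw trait values, kg.
#' @return an object of class `genotypic_effects`: a data frame with one
#'   row per coding (`effect`, `se`, `p`, `aic`, `estimable`).
#' @export
genotypic_effects <- function(geno_count, mw) {
  keep <- !is.na(geno_count) & !is.na(mw)
  g <- geno_count[keep]
  y <- mw[keep]
  if (!all(g %in% 0:2)) stop("genotype codes must be 0, 1 or 2",
                             call. = FALSE)
  if (length(unique(g)) < 2) stop("monomorphic locus: effects inestimable",
                                  call. = FALSE)
  codings <- list(additive = g,
                  dominance = as.numeric(g >= 1),
                  recessive = as.numeric(g == 2))
  rows <- lapply(names(codings), function(nm) {
    x <- codings[[nm]]
    if (stats::sd(x) == 0) {
      return(data.frame(coding = nm, effect = NA_real_, se = NA_real_,
                        p = NA_real_, aic = NA_real_, estimable = FALSE))
    }
    fit <- stats::lm(y ~ x)
    cf <- summary(fit)$coefficients
    data.frame(coding = nm, effect = cf["x", "Estimate"],
               se = cf["x", "Std. Error"], p = cf["x", "Pr(>|t|)"],
               aic = aic_rss(fit), estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("genotypic_effects", "data.frame")
  out
}
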