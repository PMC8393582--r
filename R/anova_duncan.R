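#' One-way genotype-trait ANOVA with Duncan mean separation
#'
#' Tests the association between genotype classes at one locus and a
#' quantitative trait by one-way ANOVA ([stats::aov()]), then assigns
#' Duncan multiple-range grouping letters to the class means.
#'
#' Duncan's test compares the range of every set of `p` consecutive
#' ordered means against the least significant range
#' `R_p = q(1 - alpha_p, p, df_err) * sqrt(MSE / r_h)`, where `q` is the
#' studentized-range quantile, `alpha_p = 1 - (1 - alpha)^(p - 1)` is the
#' protection level for a span of `p` means, and `r_h` is the harmonic
#' mean of the class sizes.  Classes covered by a common non-significant
#' range share a letter; classes sharing no letter differ at the
#' protected level.
#'
#' Classes with fewer than 2 observations are dropped from the analysis
#' with a warning.
#'
#' @param genotype character/factor vector of genotype classes.
#' @param mw numeric trait values (kg).
#' @param alpha significance level for the range tests.
#' @return an object of class `genotype_anova`: a list with `F`, `p`,
#'   `df`, `mse`, and a `groups` data frame (`genotype`, `n`, `mean`,
#'   `se`, `letters`, ordered by decreasing mean).
#' @export
genotype_trait_anova <- function(genotype, mw, alpha = 0.05) {
  keep <- !is.na(genotype) & !is.na(mw)
  g <- as.character(genotype[keep])
  y <- mw[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping genotype class(es) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep2 <- !(g %in% small)
    g <- g[keep2]
    y <- y[keep2]
    sizes <- table(g)
  }
  if (length(sizes) < 2) {
    stop("need at least 2 genotype classes with >= 2 observations",
         call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("zero residual variance: F statistic undefined", call. = FALSE)
  }
  fit <- stats::aov(y ~ factor(g))
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2]
  if (!is.finite(mse) || mse <= 0) {
    stop("zero residual variance: F statistic undefined", call. = FALSE)
  }
  df_err <- an[["Df"]][2]

  means <- tapply(y, g, mean)
  ses <- tapply(y, g, function(v) stats::sd(v) / sqrt(length(v)))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  letters_vec <- duncan_letters(m, as.integer(sizes[names(m)]), mse, df_err,
                                alpha)
  groups <- data.frame(
    genotype = names(m), n = as.integer(sizes[names(m)]),
    mean = as.numeric(m), se = as.numeric(ses[names(m)]),
    letters = letters_vec, stringsAsFactors = FALSE
  )
  rownames(groups) <- NULL
  structure(list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                 df = an[["Df"]], mse = mse, alpha = alpha,
                 groups = groups),
            class = "genotype_anova")
}

#' @export
print.genotype_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# Duncan multiple-range lettering over means sorted in decreasing order.
# Returns one letter string per mean.
duncan_letters <- function(sorted_means, n_sizes, mse, df_err, alpha) {
  k <- length(sorted_means)
  r_h <- k / sum(1 / n_sizes)                 # harmonic mean class size
  spans <- 2:max(2, k)
  alpha_p <- 1 - (1 - alpha)^(spans - 1)      # protection levels
  lsr <- stats::qtukey(1 - alpha_p, spans, df_err) * sqrt(mse / r_h)
  lsr <- c(0, lsr)                            # lsr[p] for span p (p >= 2)

  # maximal homogeneous intervals: from each start, extend while the
  # extreme pair of the range stays below its least significant range
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (sorted_means[i] - sorted_means[j + 1]) <= lsr[j + 1 - i + 1]) {
      j <- j + 1
    }
    contained <- any(vapply(intervals, function(iv) {
      iv[1] <= i && j <= iv[2]
    }, logical(1)))
    if (!contained) intervals[[length(intervals) + 1]] <- c(i, j)
  }
  letters_out <- character(k)
  for (s in seq_along(intervals)) {
    iv <- intervals[[s]]
    cover <- iv[1]:iv[2]
    letters_out[cover] <- paste0(letters_out[cover], letters[s])
  }
  letters_out
}
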