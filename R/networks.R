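## genotype-mode codings across {ref-hom, het, alt-hom}
mode_codes <- list(
  additive = c(0, 1, 2),       # het at the homozygote midpoint
  dominant_alt = c(0, 1, 1),   # het expresses like the alt homozygote
  dominant_ref = c(0, 0, 1),   # het expresses like the ref homozygote
  over_dominant = c(0, 1, 0)   # het outside the homozygote interval
)

code_genotypes <- function(geno_count, mode) {
  mode_codes[[mode]][geno_count + 1L]
}

#' Select the best-fitting genotype mode for a single SNP
#'
#' Regresses the trait on each candidate genotype-mode coding (additive
#' `(0,1,2)`, dominant towards either homozygote `(0,1,1)`/`(0,0,1)`,
#' over-dominant `(0,1,0)`) and returns the coding minimising the
#' constant-free [aic_rss()].  AIC ties are broken in the order additive,
#' dominant, over-dominant, preferring the simpler genetic
#' interpretation.
#'
#' @param geno_count integer vector of alternative-allele counts (0/1/2).
#' @param mw trait values, kg.
#' @param locus_id optional locus label carried into the result.
#' @return an object of class `mode_coding`: list with `locus_id`,
#'   `mode`, `codes` (the numeric codes for ref-hom/het/alt-hom),
#'   `effect`, `se`, `p` (slope test of the coded predictor), `aic`,
#'   and the per-mode AIC table.
#' @export
fit_single_snp_modes <- function(geno_count, mw, locus_id = NA_character_) {
  keep <- !is.na(geno_count) & !is.na(mw)
  g <- geno_count[keep]
  y <- mw[keep]
  if (!all(g %in% 0:2)) stop("genotype codes must be 0, 1 or 2",
                             call. = FALSE)
  if (length(unique(g)) < 2) stop("monomorphic locus: mode inestimable",
                                  call. = FALSE)
  fits <- lapply(names(mode_codes), function(mode) {
    x <- code_genotypes(g, mode)
    if (stats::sd(x) == 0) return(NULL)
    fit <- stats::lm(y ~ x)
    cf <- summary(fit)$coefficients
    list(mode = mode, effect = cf["x", "Estimate"],
         se = cf["x", "Std. Error"], p = cf["x", "Pr(>|t|)"],
         aic = aic_rss(fit))
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  # ties broken by candidate order: additive, dominant_*, over_dominant
  best <- fits[[which(aics <= min(aics) + 1e-9)[1]]]
  structure(list(
    locus_id = locus_id, mode = best$mode,
    codes = mode_codes[[best$mode]],
    effect = best$effect, se = best$se, p = best$p, aic = best$aic,
    aic_table = data.frame(
      mode = vapply(fits, `[[`, character(1), "mode"),
      aic = aics, stringsAsFactors = FALSE
    )
  ), class = "mode_coding")
}

#' @export
print.mode_coding <- function(x, ...) {
  cat(sprintf("%s: %s mode (codes %s), effect %.3f +/- %.3f, p = %.3g\n",
              x$locus_id %||% "locus", x$mode,
              paste(x$codes, collapse = "/"), x$effect, x$se, x$p))
  invisible(x)
}

fit_network <- function(X, y, members, modes) {
  d <- data.frame(y = y, X[, members, drop = FALSE], check.names = FALSE)
  fit <- stats::lm(y ~ ., data = d)
  cf <- summary(fit)$coefficients
  coef_names <- rownames(cf)[-1]
  # lm backtick-quotes non-syntactic names; map back to member ids
  clean <- gsub("^`|`$", "", coef_names)
  sub_g <- vapply(seq_along(members), function(i) {
    codes <- mode_codes[[modes[i]]]
    unname(stats::coef(fit)[1 + i] * (codes[3] - codes[1]) * 1000)
  }, numeric(1))
  structure(list(
    members = members, modes = modes,
    intercept = unname(stats::coef(fit)[1]),
    coefficients = stats::setNames(unname(stats::coef(fit)[-1]),
                                   clean),
    member_p = stats::setNames(unname(cf[-1, "Pr(>|t|)"]), clean),
    substitution_g = stats::setNames(sub_g, members),
    fitted = unname(stats::fitted(fit)),
    actual = y,
    r2 = summary(fit)$r.squared,
    aic = aic_rss(fit),
    fit = fit
  ), class = "snp_network")
}

#' @export
print.snp_network <- function(x, ...) {
  cat(sprintf("SNP network of %d loci: R2 = %.3f, AIC = %.2f\n",
              length(x$members), x$r2, x$aic))
  print(data.frame(locus = x$members, mode = x$modes,
                   coefficient = unname(x$coefficients[x$members]),
                   substitution_g = unname(x$substitution_g[x$members])),
        row.names = FALSE)
  invisible(x)
}

#' Stepwise multi-marker SNP-network search
#'
#' Builds multi-SNP linear models ("SNP networks") for a quantitative
#' trait from best-mode coded genotypes.  Loci are first screened by
#' their single-SNP association ([fit_single_snp_modes()]; entry requires
#' `p < alpha`); a stepwise search with entry/stay threshold `alpha` on
#' partial F-tests (equivalently, the t-test of each member's coefficient
#' given the others) selects a model of at most `max_size` loci; finally
#' every subset of the surviving loci of size 2 to `max_size` whose
#' members are all jointly significant is enumerated and ranked by
#' [aic_rss()].
#'
#' @param genotypes integer matrix (individuals x loci) of
#'   alternative-allele counts, with column names.
#' @param mw trait vector aligned with the rows of `genotypes`.
#' @param candidate_loci optional subset of column names to consider.
#' @param direction `"forward"` (grow from the empty model) or
#'   `"backward"` (prune from the full candidate model).
#' @param alpha entry/stay significance threshold.
#' @param max_size largest network size enumerated.
#' @return an object of class `snp_network_search`: list with
#'   `single_snp` (per-locus mode/effect/p table), `selected` (loci
#'   surviving the stepwise search) and `networks` (list of
#'   `snp_network` models, AIC-ascending).
#' @export
stepwise_network_search <- function(genotypes, mw, candidate_loci = NULL,
                                    direction = c("forward", "backward"),
                                    alpha = 0.05, max_size = 4) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)),
            length(mw) == nrow(genotypes))
  loci <- candidate_loci %||% colnames(genotypes)
  loci <- intersect(loci, colnames(genotypes))

  keep <- !is.na(mw) & stats::complete.cases(genotypes[, loci, drop = FALSE])
  y <- mw[keep]
  G <- genotypes[keep, loci, drop = FALSE]

  ## single-SNP screen with mode selection
  polymorphic <- vapply(loci, function(l) length(unique(G[, l])) > 1,
                        logical(1))
  modes <- lapply(loci[polymorphic], function(l) {
    fit_single_snp_modes(G[, l], y, locus_id = l)
  })
  names(modes) <- loci[polymorphic]
  single <- data.frame(
    locus_id = names(modes),
    mode = vapply(modes, `[[`, character(1), "mode"),
    effect = vapply(modes, `[[`, numeric(1), "effect"),
    p = vapply(modes, `[[`, numeric(1), "p"),
    aic = vapply(modes, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE
  )
  rownames(single) <- NULL
  candidates <- single$locus_id[single$p < alpha]

  ## coded design matrix
  X <- vapply(candidates, function(l) {
    code_genotypes(G[, l], modes[[l]]$mode)
  }, numeric(length(y)))
  if (length(candidates) == 1) X <- matrix(X, ncol = 1,
                                           dimnames = list(NULL, candidates))

  member_pvals <- function(set) {
    fit_network(X, y, set, vapply(modes[set], `[[`, character(1),
                                  "mode"))$member_p[set]
  }
  full_rank <- function(set) {
    qr(cbind(1, X[, set, drop = FALSE]))$rank == length(set) + 1L
  }

  selected <- character(0)
  if (length(candidates) >= 1) {
    if (direction == "forward") {
      pool <- candidates
      while (length(selected) < max_size && length(pool) > 0) {
        trial_p <- vapply(pool, function(l) {
          set <- c(selected, l)
          if (!full_rank(set)) return(NA_real_)
          member_pvals(set)[l]
        }, numeric(1))
        if (all(is.na(trial_p)) || min(trial_p, na.rm = TRUE) >= alpha) break
        add <- pool[which.min(trial_p)]
        selected <- c(selected, add)
        pool <- setdiff(pool, add)
      }
    } else {
      selected <- candidates
      # collinear candidates: drop the later-entering (higher single-SNP p)
      while (!full_rank(selected) && length(selected) > 1) {
        drop_ord <- selected[order(-single$p[match(selected,
                                                   single$locus_id)])]
        dropped <- FALSE
        for (l in drop_ord) {
          if (full_rank(setdiff(selected, l))) {
            warning("dropping collinear locus ", l)
            selected <- setdiff(selected, l)
            dropped <- TRUE
            break
          }
        }
        if (!dropped) break
      }
    }
    ## stay step: prune members that lose significance given the others
    repeat {
      if (length(selected) <= 1) break
      pv <- member_pvals(selected)
      if (max(pv) < alpha && length(selected) <= max_size) break
      worst <- names(pv)[which.max(pv)]
      if (max(pv) >= alpha) {
        selected <- setdiff(selected, worst)
      } else {
        selected <- setdiff(selected, worst)  # over max_size: shed weakest
      }
    }
    if (length(selected) == 1 &&
        member_pvals(selected)[1] >= alpha) {
      selected <- character(0)
    }
  }

  ## enumerate surviving subsets of size 2..max_size
  networks <- list()
  if (length(selected) >= 2) {
    for (size in 2:min(max_size, length(selected))) {
      for (set in utils::combn(selected, size, simplify = FALSE)) {
        if (!full_rank(set)) next
        mod <- fit_network(X, y, set,
                           vapply(modes[set], `[[`, character(1), "mode"))
        if (all(mod$member_p[set] < alpha)) {
          networks[[length(networks) + 1]] <- mod
        }
      }
    }
    networks <- networks[order(vapply(networks, `[[`, numeric(1), "aic"))]
  }

  structure(list(single_snp = single, candidates = candidates,
                 selected = selected, networks = networks,
                 alpha = alpha, direction = direction),
            class = "snp_network_search")
}

#' @export
print.snp_network_search <- function(x, ...) {
  cat(sprintf(
    "SNP-network search (%s, alpha = %.2f): %d candidates, %d selected, %d networks\n",
    x$direction, x$alpha, length(x$candidates), length(x$selected),
    length(x$networks)))
  if (length(x$networks)) {
    cat("Top network:\n")
    print(x$networks[[1]])
  }
  invisible(x)
}

#' Homozygote substitution effects of a SNP network
#'
#' For each member locus, the model-predicted trait change (in grams)
#' when the alternative homozygote replaces the reference homozygote,
#' holding the other members fixed: the locus coefficient times the code
#' difference between the two homozygote classes.  For an additive-coded
#' locus this is twice the per-allele coefficient.  Over-dominant loci
#' have identical homozygote codes, so their substitution effect is not a
#' useful selection quantity and is reported as `NA` unless
#' `include_over_dominant = TRUE` (then 0).
#'
#' @param model a `snp_network` model.
#' @param include_over_dominant report the (zero) effect of over-dominant
#'   loci instead of `NA`.
#' @return data frame `locus_id`, `mode`, `substitution_g`.
#' @export
substitution_effects <- function(model, include_over_dominant = FALSE) {
  stopifnot(inherits(model, "snp_network"))
  out <- data.frame(
    locus_id = model$members, mode = model$modes,
    substitution_g = unname(model$substitution_g[model$members]),
    stringsAsFactors = FALSE
  )
  if (!include_over_dominant) {
    out$substitution_g[out$mode == "over_dominant"] <- NA_real_
  }
  out
}

#' Spearman correlation matrix of genotype values and trait
#'
#' Pairwise Spearman rank correlations (midrank ties, pairwise complete
#' observations) between numeric genotype values and the trait, plus a
#' display order from average-linkage hierarchical clustering of the
#' distance `1 - |rho|` -- the structure used to draw correlation heat
#' maps.
#'
#' @param values data frame or matrix of numeric columns (genotype codes
#'   per SNP, and usually the trait as a column); at least 3 rows.
#' @return list with `rho` (correlation matrix; constant columns give
#'   `NA` with a warning), `order` (display order of the columns) and
#'   `hclust` (the clustering tree, or `NULL` when fewer than 3
#'   columns).
#' @export
spearman_matrix <- function(values) {
  m <- as.matrix(values)
  if (nrow(m) < 3) stop("need at least 3 observations", call. = FALSE)
  constant <- apply(m, 2, function(col) {
    stats::sd(col, na.rm = TRUE) == 0 || all(is.na(col))
  })
  if (any(constant)) {
    warning("constant column(s), correlation undefined: ",
            paste(colnames(m)[constant], collapse = ", "))
  }
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho)[!constant] <- 1

  hc <- NULL
  ord <- seq_len(ncol(m))
  if (ncol(m) >= 3) {
    d <- 1 - abs(rho)
    d[is.na(d)] <- 1
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ord <- hc$order
  }
  list(rho = rho, order = ord, hclust = hc)
}
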