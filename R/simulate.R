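#' Simulate a sib-structured study population
#'
#' Generates a nested paternal half-sib population (each sire mated to
#' `dams_per_sire` dams, `progeny_per_dam` full sibs per dam), biallelic
#' SNP genotypes with Mendelian transmission from founders drawn at
#' Hardy-Weinberg proportions, and a quantitative trait built from causal
#' locus effects, a polygenic breeding value and Gaussian environmental
#' noise.
#'
#' The genetic architecture is calibrated so that the *additive* genetic
#' variance equals `heritability * trait_sd^2`: causal loci contribute
#' their analytic additive variance (`2pq * alpha^2` per locus, with
#' `alpha` the average allele-substitution effect) and a polygenic term
#' absorbs the remainder.  Dominance deviations of `dominant` and
#' `over_dominant` causal loci are simulated on top and, like the
#' environmental term, do not count towards narrow-sense heritability.
#' Genotypic values across \{ref-hom, het, alt-hom\} follow the mode:
#' additive `(0, a, 2a)`, dominant `(0, 2a, 2a)`, over-dominant
#' `(0, a, 0)`.
#'
#' Sex is a fixed mean offset only (`trait_mean` is the male mean; females
#' are shifted down by `sex_effect`); no genotype-by-sex interaction is
#' generated.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `true_population`: a list with
#'   \describe{
#'     \item{individuals}{data frame of `id`, `sire_id`, `dam_id`, `sex`,
#'       `generation` (`"founder"`/`"progeny"`), `mw` (marketing weight,
#'       kg; `NA` for founders) and `true_bv` (true additive breeding
#'       value, kg).}
#'     \item{genotypes}{integer matrix (individuals x loci) of
#'       alternative-allele counts, founders included.}
#'     \item{loci}{data frame of `locus_id`, `chrom`, `pos`, `ref`, `alt`,
#'       `founder_freq`, `causal`, `effect`, `mode`.}
#'     \item{variances}{the generative variance components
#'       (`sigma2_A`, `sigma2_D`, `sigma2_e`, `h2`).}
#'   }
#' @examples
#' pop <- simulate_population(simulation_config(n_sires = 5,
#'   dams_per_sire = 2, progeny_per_dam = 4, n_loci = 20, seed = 42))
#' head(pop$individuals)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "population"))

  n_sires <- config$n_sires
  n_dams <- n_sires * config$dams_per_sire
  n_prog <- n_dams * config$progeny_per_dam
  n_loci <- config$n_loci

  ## loci: independent biallelic SNPs on a handful of chromosomes
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  loci <- data.frame(
    locus_id = sprintf("L%05d", seq_len(n_loci)),
    chrom = sprintf("chr%d", ((seq_len(n_loci) - 1L) %% 10L) + 1L),
    pos = sample.int(5e7, n_loci, replace = TRUE),
    ref = ref, alt = unname(alt),
    founder_freq = stats::runif(n_loci, config$founder_freq_range[1],
                                config$founder_freq_range[2]),
    causal = FALSE, effect = 0, mode = NA_character_,
    stringsAsFactors = FALSE
  )
  if (config$n_causal > 0) {
    idx <- sort(sample.int(n_loci, config$n_causal))
    loci$causal[idx] <- TRUE
    loci$effect[idx] <- config$causal_effect_sizes
    loci$mode[idx] <- config$causal_modes
  }

  ## genotypic values per mode across {ref-hom, het, alt-hom}
  geno_values <- function(a, mode) {
    switch(mode,
           additive = c(0, a, 2 * a),
           dominant = c(0, 2 * a, 2 * a),
           over_dominant = c(0, a, 0),
           stop("unknown mode: ", mode))
  }

  f <- loci$founder_freq
  alpha <- numeric(n_loci)     # average substitution effect
  dom_dev <- numeric(n_loci)   # dominance deviation parameter d
  vmat <- matrix(0, nrow = n_loci, ncol = 3)
  for (j in which(loci$causal)) {
    v <- geno_values(loci$effect[j], loci$mode[j])
    vmat[j, ] <- v
    alpha[j] <- f[j] * (v[3] - v[2]) + (1 - f[j]) * (v[2] - v[1])
    dom_dev[j] <- v[2] - (v[1] + v[3]) / 2
  }
  sigma2_P <- config$trait_sd^2
  sigma2_A_target <- config$heritability * sigma2_P
  sigma2_A_causal <- sum(2 * f * (1 - f) * alpha^2)
  sigma2_D <- sum((2 * f * (1 - f) * dom_dev)^2)
  sigma2_poly <- sigma2_A_target - sigma2_A_causal
  if (sigma2_poly < 0) {
    warning("causal additive variance exceeds heritability * trait_sd^2; ",
            "polygenic variance clipped at 0")
    sigma2_poly <- 0
  }
  sigma2_e <- max(0, sigma2_P - sigma2_A_target - sigma2_D)

  ## founder genotypes at Hardy-Weinberg proportions
  n_founders <- n_sires + n_dams
  sire_ids <- sprintf("S%03d", seq_len(n_sires))
  dam_ids <- sprintf("D%04d", seq_len(n_dams))
  prog_ids <- sprintf("P%05d", seq_len(n_prog))
  founder_geno <- matrix(
    stats::rbinom(n_founders * n_loci, 2L, rep(f, each = n_founders)),
    nrow = n_founders, ncol = n_loci
  )

  ## pedigree: dams nested within sires, full sibs within dam
  prog_dam <- rep(seq_len(n_dams), each = config$progeny_per_dam)
  prog_sire <- ((prog_dam - 1L) %/% config$dams_per_sire) + 1L

  ## Mendelian transmission: one allele from each parent
  transmit <- function(parent_geno) {
    # parent_geno: n_prog x n_loci alt-allele counts; het transmits alt w.p. 1/2
    matrix(stats::rbinom(length(parent_geno), 1L, parent_geno / 2),
           nrow = nrow(parent_geno))
  }
  sire_geno <- founder_geno[prog_sire, , drop = FALSE]
  dam_geno <- founder_geno[n_sires + prog_dam, , drop = FALSE]
  prog_geno <- transmit(sire_geno) + transmit(dam_geno)

  genotypes <- rbind(founder_geno, prog_geno)
  rownames(genotypes) <- c(sire_ids, dam_ids, prog_ids)
  colnames(genotypes) <- loci$locus_id

  ## polygenic breeding values: parent average + Mendelian sampling
  u_founder <- stats::rnorm(n_founders, 0, sqrt(sigma2_poly))
  u_prog <- 0.5 * (u_founder[prog_sire] + u_founder[n_sires + prog_dam]) +
    stats::rnorm(n_prog, 0, sqrt(sigma2_poly / 2))

  ## causal contributions (centred at the founder-frequency expectation)
  causal_parts <- function(geno) {
    bv <- numeric(nrow(geno))
    dd <- numeric(nrow(geno))
    for (j in which(loci$causal)) {
      g <- geno[, j]
      gv <- vmat[j, g + 1L]
      mean_v <- (1 - f[j])^2 * vmat[j, 1] +
        2 * f[j] * (1 - f[j]) * vmat[j, 2] + f[j]^2 * vmat[j, 3]
      bv_j <- alpha[j] * (g - 2 * f[j])
      bv <- bv + bv_j
      dd <- dd + (gv - mean_v - bv_j)
    }
    list(bv = bv, dd = dd)
  }
  cp_founder <- causal_parts(founder_geno)
  cp_prog <- causal_parts(prog_geno)

  sex <- sample(c("M", "F"), n_prog, replace = TRUE)
  env <- stats::rnorm(n_prog, 0, sqrt(sigma2_e))
  mu <- config$trait_mean - ifelse(sex == "F", config$sex_effect, 0)
  bv_prog <- u_prog + cp_prog$bv
  mw <- mu + bv_prog + cp_prog$dd + env

  individuals <- data.frame(
    id = c(sire_ids, dam_ids, prog_ids),
    sire_id = c(rep(NA_character_, n_founders), sire_ids[prog_sire]),
    dam_id = c(rep(NA_character_, n_founders), dam_ids[prog_dam]),
    sex = c(rep("M", n_sires), rep("F", n_dams), sex),
    generation = c(rep("founder", n_founders), rep("progeny", n_prog)),
    mw = c(rep(NA_real_, n_founders), mw),
    true_bv = c(u_founder + cp_founder$bv, bv_prog),
    stringsAsFactors = FALSE
  )

  structure(list(
    individuals = individuals,
    genotypes = genotypes,
    loci = loci,
    variances = list(sigma2_A = sigma2_A_target, sigma2_D = sigma2_D,
                     sigma2_e = sigma2_e, h2 = config$heritability),
    config = config
  ), class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  n_prog <- sum(x$individuals$generation == "progeny")
  cat(sprintf(
    "Synthetic sib population: %d founders + %d progeny, %d loci (%d causal)\n",
    sum(x$individuals$generation == "founder"), n_prog,
    nrow(x$loci), sum(x$loci$causal)))
  invisible(x)
}

#' Simulate pooled base depths for two extreme bulks
#'
#' Emulates pooled sequencing of two DNA bulks (equal DNA contribution per
#' individual): per locus and bulk, total depth is Poisson around
#' `mean_depth` and base counts are multinomial at the bulk's true
#' alternative-allele frequency (allele count over twice the bulk size),
#' with `error_rate` probability of mis-reading a base uniformly as one of
#' the other three.  The locus quality value is the Phred score of
#' `error_rate` (infinite when the error rate is zero).
#'
#' @param pop a `true_population` from [simulate_population()].
#' @param low_ids,high_ids ids of the individuals pooled in the low- and
#'   high-EBV bulks; must be disjoint and non-empty.
#' @param mean_depth mean per-locus sequencing depth per bulk (reads).
#' @param error_rate per-base sequencing error probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a locus-depth data frame with one row per locus and columns
#'   `locus_id`, `chrom`, `pos`, `ref`, `alt`, `A_H` ... `T_H`,
#'   `A_L` ... `T_L` (per-base read depths in the high- and low-EBV
#'   bulks) and `Q` (Phred quality).
#' @export
simulate_bulk_depths <- function(pop, low_ids, high_ids,
                                 mean_depth = 25, error_rate = 0.001,
                                 seed = 1L) {
  stopifnot(inherits(pop, "true_population"))
  if (length(low_ids) == 0 || length(high_ids) == 0) {
    stop("both bulks must be non-empty", call. = FALSE)
  }
  if (length(intersect(low_ids, high_ids)) > 0) {
    stop("bulks must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(low_ids, high_ids), rownames(pop$genotypes))
  if (length(missing)) {
    stop("unknown individual ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  error_rate <- check_fraction(error_rate, "error_rate", open = FALSE)
  set.seed(derive_seed(seed, "bulk_depths"))

  loci <- pop$loci
  bases <- c("A", "C", "G", "T")
  q <- if (error_rate > 0) q_score(error_rate) else Inf

  bulk_counts <- function(ids) {
    geno <- pop$genotypes[ids, , drop = FALSE]
    f_bulk <- colSums(geno) / (2 * length(ids))
    depth <- stats::rpois(nrow(loci), mean_depth)
    out <- matrix(0L, nrow = nrow(loci), ncol = 4,
                  dimnames = list(NULL, bases))
    for (i in seq_len(nrow(loci))) {
      p_true <- stats::setNames(numeric(4), bases)
      p_true[loci$alt[i]] <- f_bulk[i]
      p_true[loci$ref[i]] <- 1 - f_bulk[i]
      # observation model: correct read w.p. 1 - e, else uniform other base
      p_obs <- p_true * (1 - error_rate) + (1 - p_true) * error_rate / 3
      if (depth[i] > 0) {
        out[i, ] <- stats::rmultinom(1, depth[i], p_obs)[, 1]
      }
    }
    out
  }

  h <- bulk_counts(high_ids)
  l <- bulk_counts(low_ids)
  data.frame(
    locus_id = loci$locus_id, chrom = loci$chrom, pos = loci$pos,
    ref = loci$ref, alt = loci$alt,
    A_H = h[, "A"], C_H = h[, "C"], G_H = h[, "G"], T_H = h[, "T"],
    A_L = l[, "A"], C_L = l[, "C"], G_L = l[, "G"], T_L = l[, "T"],
    Q = q, stringsAsFactors = FALSE
  )
}

#' Simulate a qPCR CT table with planted fold changes
#'
#' Generates target- and reference-gene cycle-threshold values for
#' biological samples in technical triplicate.  The reference gene (the
#' internal-control role, e.g. GAPDH) has a constant baseline CT; the
#' target CT for a sample in group `g` is
#' `ct_reference + delta_ct_baseline - log2(fold_changes[g])`, so the
#' downstream 2^-ddCT estimate recovers `fold_changes` relative to the
#' first (calibrator) group.  Gaussian noise of `ct_noise_sd` cycles is
#' added independently to every well.
#'
#' @param groups character vector of genotype-group labels; the first is
#'   the calibrator (fold change 1 by construction).
#' @param fold_changes positive per-group expression fold changes
#'   relative to the calibrator (same length as `groups`).
#' @param ct_noise_sd per-well CT noise, cycles.
#' @param n_per_group biological samples per group.
#' @param seed integer seed.
#' @param n_replicates technical replicates per sample.
#' @param gene target gene label.
#' @param ct_reference baseline reference-gene CT, cycles.
#' @param delta_ct_baseline calibrator-group target-minus-reference CT
#'   difference, cycles.
#' @return a CT data frame with columns `sample_id`, `gene`,
#'   `genotype_group`, `replicate`, `ct_target`, `ct_reference`.
#' @export
simulate_expression <- function(groups, fold_changes, ct_noise_sd = 0.2,
                                n_per_group = 7, seed = 1L,
                                n_replicates = 3, gene = "target",
                                ct_reference = 20, delta_ct_baseline = 5) {
  stopifnot(length(groups) == length(fold_changes))
  if (any(fold_changes <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  n_per_group <- check_count(n_per_group, "n_per_group")
  n_replicates <- check_count(n_replicates, "n_replicates")
  set.seed(derive_seed(seed, "expression"))

  rows <- lapply(seq_along(groups), function(g) {
    ids <- sprintf("%s_s%02d", groups[g], seq_len(n_per_group))
    df <- expand.grid(sample_id = ids, replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(df)
    data.frame(
      sample_id = df$sample_id, gene = gene, genotype_group = groups[g],
      replicate = df$replicate,
      ct_target = ct_reference + delta_ct_baseline - log2(fold_changes[g]) +
        stats::rnorm(n, 0, ct_noise_sd),
      ct_reference = ct_reference + stats::rnorm(n, 0, ct_noise_sd),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype_group, out$sample_id, out$replicate), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
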