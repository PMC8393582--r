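#' Simulation configuration for the synthetic study population
#'
#' Builds and validates the parameter set that drives every synthetic input
#' of the pipeline: a nested paternal half-sib population (each sire mated
#' to several dams, full sibs within dam), biallelic SNPs with
#' additive/dominant/over-dominant effects on marketing weight, extreme
#' breeding-value bulks, and binomially sampled pooled base depths.
#'
#' Defaults emulate the study design this package targets: a gosling
#' population of a few hundred males with narrow-sense heritability 0.29
#' for marketing weight (mean 4.11 kg for males), bulks of 20 individuals
#' per tail, and pooled sequencing at ~25x per bulk with a base-call error
#' rate of 0.001 (Phred 30).
#'
#' @param n_sires number of sires.
#' @param dams_per_sire dams mated to each sire.
#' @param progeny_per_dam progeny per full-sib family.
#' @param heritability narrow-sense heritability of the trait, in (0, 1).
#' @param trait_mean trait mean for males, kg.
#' @param trait_sd phenotypic standard deviation, kg.
#' @param sex_effect fixed male-minus-female mean difference, kg.  The
#'   trait model has no genotype-by-sex interaction.
#' @param n_loci number of biallelic SNP loci.
#' @param n_causal number of causal loci among them.
#' @param causal_effect_sizes effect size per causal locus, kg per
#'   allele substitution (recycled to `n_causal`).
#' @param causal_modes gene-action mode per causal locus: `"additive"`,
#'   `"dominant"` or `"over_dominant"` (recycled to `n_causal`).
#' @param founder_freq_range range from which founder alternative-allele
#'   frequencies are drawn uniformly.
#' @param bulk_size individuals per extreme bulk.
#' @param mean_depth_per_bulk mean pooled sequencing depth per bulk per
#'   locus (reads).
#' @param sequencing_error_rate per-base sequencing error probability.
#' @param seed integer seed from which all randomness flows.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_sires = 5, dams_per_sire = 2,
#'                          progeny_per_dam = 4, n_loci = 50, seed = 1)
#' pop <- simulate_population(cfg)
#' @export
simulation_config <- function(n_sires = 8,
                              dams_per_sire = 5,
                              progeny_per_dam = 8,
                              heritability = 0.29,
                              trait_mean = 4.11,
                              trait_sd = 0.45,
                              sex_effect = 0.61,
                              n_loci = 1000,
                              n_causal = 5,
                              causal_effect_sizes = 0.15,
                              causal_modes = "additive",
                              founder_freq_range = c(0.2, 0.8),
                              bulk_size = 20,
                              mean_depth_per_bulk = 25,
                              sequencing_error_rate = 0.001,
                              seed = 1L) {
  cfg <- list(
    n_sires = check_count(n_sires, "n_sires"),
    dams_per_sire = check_count(dams_per_sire, "dams_per_sire"),
    progeny_per_dam = check_count(progeny_per_dam, "progeny_per_dam"),
    heritability = check_fraction(heritability, "heritability"),
    trait_mean = check_positive(trait_mean, "trait_mean"),
    trait_sd = if (trait_sd == 0) 0 else check_positive(trait_sd, "trait_sd"),
    sex_effect = as.numeric(sex_effect),
    n_loci = check_count(n_loci, "n_loci"),
    n_causal = check_count(n_causal, "n_causal", min = 0L),
    causal_effect_sizes = as.numeric(causal_effect_sizes),
    causal_modes = as.character(causal_modes),
    founder_freq_range = as.numeric(founder_freq_range),
    bulk_size = check_count(bulk_size, "bulk_size"),
    mean_depth_per_bulk = check_positive(mean_depth_per_bulk,
                                         "mean_depth_per_bulk"),
    sequencing_error_rate = check_fraction(sequencing_error_rate,
                                           "sequencing_error_rate",
                                           open = FALSE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_causal > cfg$n_loci) {
    stop("`n_causal` must not exceed `n_loci`", call. = FALSE)
  }
  n_prog <- cfg$n_sires * cfg$dams_per_sire * cfg$progeny_per_dam
  if (cfg$bulk_size > n_prog / 2) {
    stop("`bulk_size` must not exceed half the progeny count", call. = FALSE)
  }
  if (cfg$n_causal > 0) {
    cfg$causal_effect_sizes <- rep_len(cfg$causal_effect_sizes, cfg$n_causal)
    cfg$causal_modes <- rep_len(cfg$causal_modes, cfg$n_causal)
    bad <- setdiff(cfg$causal_modes,
                   c("additive", "dominant", "over_dominant"))
    if (length(bad)) {
      stop("unknown causal mode(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  } else {
    cfg$causal_effect_sizes <- numeric(0)
    cfg$causal_modes <- character(0)
  }
  if (length(cfg$founder_freq_range) != 2 ||
      any(cfg$founder_freq_range <= 0) || any(cfg$founder_freq_range >= 1) ||
      diff(cfg$founder_freq_range) < 0) {
    stop("`founder_freq_range` must be an increasing pair in (0, 1)",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_prog <- x$n_sires * x$dams_per_sire * x$progeny_per_dam
  cat("Simulation configuration\n")
  cat(sprintf("  pedigree : %d sires x %d dams x %d progeny (%d progeny)\n",
              x$n_sires, x$dams_per_sire, x$progeny_per_dam, n_prog))
  cat(sprintf("  trait    : mean %.2f kg, sd %.2f kg, h2 %.2f\n",
              x$trait_mean, x$trait_sd, x$heritability))
  cat(sprintf("  loci     : %d (%d causal)\n", x$n_loci, x$n_causal))
  cat(sprintf("  bulks    : %d per tail, %.0fx depth, error %.4g\n",
              x$bulk_size, x$mean_depth_per_bulk, x$sequencing_error_rate))
  cat(sprintf("  seed     : %d\n", x$seed))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects stage toggles, filter thresholds and paths for
#' [run_pipeline()].  Thresholds default to the standard pooled-bulk
#' screening rule (Euclidean distance >= 0.7, |delta SNP index| >= 0.5,
#' Phred quality >= 30) and a 5% overall type-I error rate with the top 31
#' ranked loci carried into verification.
#'
#' @param sim a [simulation_config()] object driving the synthetic stage.
#' @param ed_min minimum Euclidean distance for a locus to pass filtering.
#' @param delta_min minimum |delta SNP index|.
#' @param q_min minimum Phred quality value.
#' @param alpha overall type-I error rate for multiple-testing control.
#' @param top_k number of top-ranked loci retained as candidates.
#' @param n_per_tail individuals selected into each extreme-EBV bulk.
#' @param out_dir output directory for the report bundle.
#' @param seed top-level seed; defaults to the simulation seed.
#' @return an object of class `run_config`.
#' @seealso [run_pipeline()]
#' @export
pipeline_config <- function(sim = simulation_config(),
                            ed_min = 0.7,
                            delta_min = 0.5,
                            q_min = 30,
                            alpha = 0.05,
                            top_k = 31,
                            n_per_tail = sim$bulk_size,
                            out_dir = "bulkseg-run",
                            seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"))
  cfg <- list(
    sim = sim,
    ed_min = check_positive(ed_min, "ed_min"),
    delta_min = check_fraction(delta_min, "delta_min", open = FALSE),
    q_min = as.numeric(q_min),
    alpha = check_fraction(alpha, "alpha"),
    top_k = check_count(top_k, "top_k"),
    n_per_tail = check_count(n_per_tail, "n_per_tail"),
    out_dir = as.character(out_dir),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain a `sim:` section with [simulation_config()] fields
#' and top-level [pipeline_config()] fields; anything omitted keeps its
#' default.
#'
#' @param path path to a YAML config file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  sim <- do.call(simulation_config, sim_args)
  rest <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), rest))
}
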