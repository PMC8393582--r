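stage_order <- c("simulate", "ebv", "score", "test", "assoc", "networks",
                 "express")
stage_deps <- list(
  simulate = character(0), ebv = "simulate", score = "ebv", test = "score",
  assoc = "test", networks = "assoc", express = character(0)
)

#' Run the full synthetic BSA study pipeline
#'
#' Executes the study chain end to end on synthetic data: simulate the
#' sib-structured population; estimate variance components and breeding
#' values and select the extreme-EBV bulks; simulate pooled bulk depths
#' and score/filter loci (Euclidean distance, delta SNP index, quality);
#' chi-square bulk association with FDR/Bonferroni control and staged
#' candidate selection; per-candidate genotype-trait ANOVA with Duncan
#' letters and effect decomposition; stepwise SNP-network search with
#' substitution effects and a Spearman matrix; and a relative-expression
#' comparison with a planted fold change.  A report bundle is written to
#' `config$out_dir`; every output file carries the package version, the
#' seed and a configuration hash in its header, and the stage log records
#' the locus counts entering and leaving each filter.  Two runs with the
#' same configuration produce byte-identical bundles.
#'
#' @param config a [pipeline_config()] object.
#' @param stages subset of pipeline stages to run, in dependency order
#'   (`"simulate"`, `"ebv"`, `"score"`, `"test"`, `"assoc"`,
#'   `"networks"`, `"express"`).  Missing dependencies raise an error
#'   before any computation.
#' @param expression_fold_change planted fold change for the expression
#'   stage.
#' @param quiet suppress progress messages.
#' @return an object of class `bsa_run`: a list of all stage results and
#'   output paths.
#' @export
run_pipeline <- function(config, stages = stage_order,
                         expression_fold_change = 1.5, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  for (s in stages) {
    missing_dep <- setdiff(stage_deps[[s]], stages)
    if (length(missing_dep)) {
      stop(sprintf("stage '%s' requires stage '%s' to run first",
                   s, paste(missing_dep, collapse = ", ")), call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    bulkseg = as.character(utils::packageVersion("bulkseg")),
    seed = config$seed,
    # hash the scientific parameters only, so identically-seeded runs into
    # different directories still produce identical bundles
    config = config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  )
  log_lines <- character(0)
  log_it <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  res <- list(config = config, out_dir = out_dir, meta = meta)

  if ("simulate" %in% stages) {
    res$population <- simulate_population(config$sim)
    prog <- res$population$individuals[
      res$population$individuals$generation == "progeny", , drop = FALSE]
    log_it("simulate: %d progeny, %d loci (%d causal)",
           nrow(prog), nrow(res$population$loci),
           sum(res$population$loci$causal))
    write_phenotypes(res$population$individuals,
                     file.path(out_dir, "phenotypes.csv"), meta)
    write_genotypes(res$population$genotypes, res$population$loci,
                    file.path(out_dir, "genotypes.tsv"), meta)
    males <- prog[prog$sex == "M", , drop = FALSE]
    res$normality <- tryCatch(check_normality(males$mw), error = identity)
    res$males <- males
  }

  if ("ebv" %in% stages) {
    ind <- res$population$individuals
    prog <- ind[ind$generation == "progeny", , drop = FALSE]
    res$varcomp <- estimate_variance_components(prog)
    res$ebv <- estimate_ebv(prog, res$varcomp)
    log_it("ebv: h2 = %.3f, h2_w = %.3f over %d phenotyped individuals",
           res$varcomp$h2, res$varcomp$h2_w, nrow(res$ebv))
    write_phenotypes(merge(prog, res$ebv, by = "id", sort = TRUE),
                     file.path(out_dir, "ebv.csv"), meta)
    male_ebv <- res$ebv[res$ebv$id %in% res$males$id, , drop = FALSE]
    res$bulks <- select_extreme_groups(male_ebv, config$n_per_tail)
    log_it("ebv: selected 2 x %d extreme males from %d", config$n_per_tail,
           nrow(male_ebv))
  }

  if ("score" %in% stages) {
    depths <- simulate_bulk_depths(
      res$population, res$bulks$low, res$bulks$high,
      mean_depth = config$sim$mean_depth_per_bulk,
      error_rate = config$sim$sequencing_error_rate,
      seed = derive_seed(config$seed, "pipeline_bulks"))
    res$scored <- score_loci(depths, config$ed_min, config$delta_min,
                             config$q_min)
    n_in <- nrow(res$scored)
    n_pass <- sum(res$scored$passes_filter)
    log_it("score: %d loci in, %d pass filter, %d rejected",
           n_in, n_pass, n_in - n_pass)
    write_locus_depths(res$scored, file.path(out_dir, "scored_loci.tsv"),
                       meta)
  }

  if ("test" %in% stages) {
    passing <- filter_loci(res$scored, config$ed_min, config$delta_min,
                           config$q_min)
    res$association <- test_bulk_loci(passing)
    res$candidates <- if (nrow(res$association) == 0) {
      list(bonferroni = character(0), top_k = character(0))
    } else {
      list(
        bonferroni = select_candidates(res$association, "bonferroni_hits",
                                       alpha = config$alpha),
        top_k = select_candidates(res$association, "top_k",
                                  k = min(config$top_k,
                                          nrow(res$association)))
      )
    }
    res$association$sel_bonferroni <-
      res$association$locus_id %in% res$candidates$bonferroni
    res$association$sel_top_k <-
      res$association$locus_id %in% res$candidates$top_k
    log_it("test: %d loci tested, %d Bonferroni hits, top-%d shortlist",
           nrow(res$association), length(res$candidates$bonferroni),
           length(res$candidates$top_k))
    assoc_out <- res$association[
      , setdiff(names(res$association), "passes_filter"), drop = FALSE]
    write_table_meta(assoc_out, file.path(out_dir, "association.tsv"),
                     meta = meta)
  }

  if ("assoc" %in% stages) {
    ## per-candidate genotype-trait association in the male stratum
    males <- res$males
    geno <- res$population$genotypes[males$id, , drop = FALSE]
    loci <- res$population$loci
    focus <- utils::head(res$candidates$top_k, 10L)
    reports <- lapply(focus, function(l) {
      g <- geno[, l]
      lab <- c("ref_hom", "het", "alt_hom")[g + 1L]
      an <- tryCatch(genotype_trait_anova(lab, males$mw),
                     error = identity)
      eff <- tryCatch(genotypic_effects(g, males$mw), error = identity)
      ref <- loci$ref[loci$locus_id == l]
      alt <- loci$alt[loci$locus_id == l]
      fr <- compute_frequencies(
        paste(ifelse(g >= 1, alt, ref), ifelse(g == 2, alt, ref), sep = "/"))
      list(locus_id = l, anova = an, effects = eff, freqs = fr)
    })
    names(reports) <- focus
    res$candidate_reports <- reports
    ok <- vapply(reports, function(r) !inherits(r$anova, "error"),
                 logical(1))
    log_it("assoc: %d candidate loci profiled (%d with valid ANOVA)",
           length(reports), sum(ok))
    eff_rows <- do.call(rbind, lapply(reports[ok], function(r) {
      cbind(locus_id = r$locus_id, F = r$anova$F, p_anova = r$anova$p,
            r$effects)
    }))
    if (!is.null(eff_rows)) {
      write_table_meta(eff_rows, file.path(out_dir, "candidate_effects.tsv"),
                       meta = meta)
    }
  }

  if ("networks" %in% stages) {
    males <- res$males
    geno <- res$population$genotypes[males$id, , drop = FALSE]
    focus <- utils::head(res$candidates$top_k, 15L)
    res$network_search <- stepwise_network_search(
      geno, males$mw, candidate_loci = focus, alpha = config$alpha)
    log_it("networks: %d candidates -> %d selected -> %d networks",
           length(res$network_search$candidates),
           length(res$network_search$selected),
           length(res$network_search$networks))
    net_json <- lapply(res$network_search$networks, function(m) {
      list(members = m$members, modes = m$modes,
           intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           substitution_g = as.list(
             substitution_effects(m)$substitution_g |>
               stats::setNames(m$members)),
           r2 = m$r2, aic = m$aic)
    })
    jsonlite::write_json(
      list(meta = meta, networks = net_json),
      file.path(out_dir, "networks.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    if (length(res$network_search$selected) >= 2) {
      sel <- res$network_search$selected
      vals <- cbind(as.data.frame(geno[, sel, drop = FALSE]),
                    mw = males$mw)
      res$spearman <- spearman_matrix(vals)
      rho_df <- data.frame(variable = rownames(res$spearman$rho),
                           res$spearman$rho, check.names = FALSE)
      write_table_meta(rho_df, file.path(out_dir, "spearman.tsv"),
                       meta = meta)
    }
  }

  if ("express" %in% stages) {
    ct <- simulate_expression(
      groups = c("ref_hom", "alt_hom"),
      fold_changes = c(1, expression_fold_change),
      seed = derive_seed(config$seed, "pipeline_expression"))
    res$rq <- relative_quantity(ct, calibrator = "ref_hom")
    res$expression_test <- compare_groups(res$rq)
    log_it("express: fold %.2f planted, mean RQ %.3f recovered, p = %.3g",
           expression_fold_change,
           mean(res$rq$rq[res$rq$genotype_group == "alt_hom"]),
           res$expression_test$p)
    write_ct(ct, file.path(out_dir, "expression_ct.csv"), meta)
    write_table_meta(res$rq, file.path(out_dir, "expression_rq.csv"),
                     sep = ",", meta = meta)
  }

  writeLines(c(sprintf("#bulkseg\t%s", meta$bulkseg),
               sprintf("#seed\t%s", meta$seed),
               sprintf("#config\t%s", meta$config),
               log_lines),
             file.path(out_dir, "pipeline.log"))
  res$log <- log_lines
  structure(res, class = "bsa_run")
}

#' @export
print.bsa_run <- function(x, ...) {
  cat("BSA pipeline run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat("  bundle: ", x$out_dir, "\n", sep = "")
  invisible(x)
}
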