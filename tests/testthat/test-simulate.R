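test_that("simulation config validates its inputs", {
  expect_error(simulation_config(heritability = 1.2), "heritability")
  expect_error(simulation_config(heritability = 0), "heritability")
  expect_error(simulation_config(n_sires = 0), "n_sires")
  expect_error(simulation_config(n_loci = 10, n_causal = 11), "n_causal")
  expect_error(simulation_config(bulk_size = 200, n_sires = 2,
                                 dams_per_sire = 2, progeny_per_dam = 2),
               "bulk_size")
  expect_error(simulation_config(causal_modes = "epistatic"), "mode")
})

test_that("population simulation is deterministic and pedigree-consistent", {
  cfg <- small_config(seed = 11)
  pop1 <- simulate_population(cfg)
  pop2 <- simulate_population(cfg)
  expect_identical(pop1, pop2)

  ind <- pop1$individuals
  prog <- ind[ind$generation == "progeny", ]
  expect_true(all(prog$sire_id %in% ind$id[ind$generation == "founder"]))
  expect_true(all(prog$dam_id %in% ind$id[ind$generation == "founder"]))
  expect_true(all(is.na(ind$mw[ind$generation == "founder"])))
  expect_true(all(!is.na(prog$mw)))
})

test_that("every progeny genotype is Mendelian-consistent with its parents", {
  pop <- simulate_population(small_config(seed = 3))
  ind <- pop$individuals
  prog <- ind[ind$generation == "progeny", ]
  g <- pop$genotypes
  # allowed transmitted alleles per parent genotype (alt-allele counts)
  allowed <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  for (i in seq_len(nrow(prog))) {
    gs <- g[prog$sire_id[i], ]
    gd <- g[prog$dam_id[i], ]
    gp <- g[prog$id[i], ]
    feasible <- mapply(function(p, s, d) {
      any(outer(allowed[[as.character(s)]], allowed[[as.character(d)]],
                "+") == p)
    }, gp, gs, gd)
    expect_true(all(feasible))
  }
})

test_that("degenerate noise-free, effect-free population is constant at the mean", {
  cfg <- simulation_config(n_sires = 3, dams_per_sire = 2,
                           progeny_per_dam = 4, n_loci = 10, n_causal = 2,
                           causal_effect_sizes = 0, trait_sd = 0,
                           sex_effect = 0, trait_mean = 4.11, bulk_size = 6,
                           seed = 5)
  pop <- simulate_population(cfg)
  mw <- pop$individuals$mw
  expect_equal(unname(mw[!is.na(mw)]), rep(4.11, sum(!is.na(mw))))
})

test_that("realized male heritability matches the configured 0.29 (half-sib ANOVA oracle)", {
  cfg <- simulation_config(n_sires = 200, dams_per_sire = 3,
                           progeny_per_dam = 8, heritability = 0.29,
                           trait_mean = 4.11, n_loci = 2, n_causal = 0,
                           seed = 91)
  pop <- simulate_population(cfg)
  ind <- pop$individuals
  males <- ind[ind$generation == "progeny" & ind$sex == "M", ]
  h2_hat <- halfsib_anova_h2(males$sire_id, males$mw)
  expect_gt(nrow(males), 1800)
  expect_lt(abs(h2_hat - 0.29), 0.1)
})

test_that("a single additive locus separates opposite homozygotes by twice its effect", {
  # law-of-large-numbers oracle: group means at n = 5000
  cfg <- simulation_config(n_sires = 25, dams_per_sire = 10,
                           progeny_per_dam = 20, n_loci = 1, n_causal = 1,
                           causal_effect_sizes = 0.2, causal_modes = "additive",
                           founder_freq_range = c(0.5, 0.5), sex_effect = 0,
                           bulk_size = 20, seed = 17)
  pop <- simulate_population(cfg)
  ind <- pop$individuals
  prog <- ind[ind$generation == "progeny", ]
  g <- pop$genotypes[prog$id, 1]
  gap <- mean(prog$mw[g == 2]) - mean(prog$mw[g == 0])
  expect_lt(abs(gap - 0.4), 0.05)
})

test_that("bulk depth simulation respects allele frequencies and quality", {
  pop <- simulate_population(small_config(seed = 2))
  prog_ids <- pop$individuals$id[pop$individuals$generation == "progeny"]
  low <- prog_ids[1:10]
  high <- prog_ids[11:20]

  expect_error(simulate_bulk_depths(pop, character(0), high), "non-empty")
  expect_error(simulate_bulk_depths(pop, low, c(high, low[1])), "disjoint")

  # error-free reads concentrate on the two true alleles; Phred 30 at 0.1% error
  d <- simulate_bulk_depths(pop, low, high, mean_depth = 30,
                            error_rate = 0.001, seed = 4)
  expect_equal(unique(d$Q), 30)
  d0 <- simulate_bulk_depths(pop, low, high, mean_depth = 50,
                             error_rate = 0, seed = 4)
  expect_true(all(is.infinite(d0$Q)))
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(d0))) {
    on_alleles <- sum(d0[i, paste0(c(d0$ref[i], d0$alt[i]), "_H")],
                      d0[i, paste0(c(d0$ref[i], d0$alt[i]), "_L")])
    total <- sum(d0[i, c(paste0(bases, "_H"), paste0(bases, "_L"))])
    expect_equal(on_alleles, total)
  }
})

test_that("deep error-free sequencing recovers the bulk allele frequency", {
  # binomial concentration oracle: freq 0.25 at depth 10000
  cfg <- simulation_config(n_sires = 4, dams_per_sire = 2,
                           progeny_per_dam = 8, n_loci = 30, n_causal = 0,
                           founder_freq_range = c(0.25, 0.25),
                           bulk_size = 16, seed = 6)
  pop <- simulate_population(cfg)
  prog_ids <- pop$individuals$id[pop$individuals$generation == "progeny"]
  bulk <- prog_ids[1:32]
  d <- simulate_bulk_depths(pop, bulk, setdiff(prog_ids, bulk),
                            mean_depth = 10000, error_rate = 0, seed = 9)
  f_true <- colSums(pop$genotypes[bulk, ]) / (2 * length(bulk))
  alt_frac <- vapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]
    row[[paste0(row$alt, "_L")]] /
      sum(row$A_L, row$C_L, row$G_L, row$T_L)
  }, numeric(1))
  expect_true(all(abs(alt_frac - f_true) < 0.02))
})

test_that("simulated CT tables carry the planted fold change", {
  expect_error(simulate_expression(c("a", "b"), c(1, -2)), "positive")

  # noise-free: RQ is exactly the planted fold change downstream
  ct <- simulate_expression(c("ref", "alt"), c(1, 2), ct_noise_sd = 0,
                            n_per_group = 3, seed = 1)
  rq <- relative_quantity(ct, calibrator = "ref")
  expect_equal(rq$rq[rq$genotype_group == "alt"], rep(2, 3))
  expect_equal(rq$rq[rq$genotype_group == "ref"], rep(1, 3))

  # Monte-Carlo oracle: noisy recovery of a 1.5-fold change
  recovered <- vapply(1:200, function(s) {
    ct <- simulate_expression(c("ref", "alt"), c(1, 1.5), ct_noise_sd = 0.2,
                              n_per_group = 7, seed = s)
    rq <- relative_quantity(ct, calibrator = "ref")
    mean(rq$rq[rq$genotype_group == "alt"])
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 1.5), 0.3)
})
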