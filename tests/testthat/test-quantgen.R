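test_that("normality check behaves as a calibrated Shapiro-Wilk wrapper", {
  expect_error(check_normality(c(1, 2)), "at least 3")
  expect_error(check_normality(rep(4.1, 10)), "constant")

  set.seed(10)
  # type-I calibration on Gaussian traits
  rej <- mean(vapply(1:400, function(i) {
    check_normality(rnorm(800))$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)

  # power against a strongly skewed trait
  pw <- mean(vapply(1:100, function(i) {
    check_normality(rexp(200))$p < 0.05
  }, logical(1)))
  expect_gte(pw, 0.95)
})

test_that("variance components are null-safe and scale-equivariant", {
  cfg <- simulation_config(n_sires = 30, dams_per_sire = 4,
                           progeny_per_dam = 6, heritability = 1e-4,
                           n_loci = 2, n_causal = 0, seed = 21)
  pop <- simulate_population(cfg)
  prog <- pop$individuals[pop$individuals$generation == "progeny", ]
  vc0 <- suppressMessages(estimate_variance_components(prog))
  expect_lte(vc0$h2, 0.05)

  cfg <- simulation_config(n_sires = 30, dams_per_sire = 4,
                           progeny_per_dam = 6, seed = 22, n_loci = 2,
                           n_causal = 0)
  pop <- simulate_population(cfg)
  prog <- pop$individuals[pop$individuals$generation == "progeny", ]
  vc1 <- estimate_variance_components(prog)
  prog2 <- transform(prog, mw = 2 * mw)
  vc2 <- estimate_variance_components(prog2)
  expect_equal(vc2$sigma2_A, 4 * vc1$sigma2_A, tolerance = 1e-4)
  expect_equal(vc2$sigma2_e, 4 * vc1$sigma2_e, tolerance = 1e-4)
  expect_equal(vc2$h2, vc1$h2, tolerance = 1e-6)

  one_family <- prog[prog$sire_id == prog$sire_id[1], ]
  expect_error(estimate_variance_components(one_family), "at least 2")
})

test_that("EBV prediction recovers true breeding values and centres near zero", {
  pop <- simulate_population(simulation_config(seed = 8))
  prog <- pop$individuals[pop$individuals$generation == "progeny", ]
  vc <- estimate_variance_components(prog)
  ebv <- estimate_ebv(prog, vc)
  merged <- merge(ebv, prog, by = "id")
  expect_gte(cor(merged$ebv, merged$true_bv), 0.4)
  males <- merged[merged$sex == "M", ]
  expect_lt(abs(mean(males$ebv)), 0.02)
  # shrunken prediction is less dispersed than the phenotype
  expect_lt(stats::var(merged$ebv), stats::var(merged$mw))
})

test_that("identical phenotypes give zero breeding values everywhere", {
  pop <- simulate_population(small_config(seed = 13))
  prog <- pop$individuals[pop$individuals$generation == "progeny", ]
  prog$mw <- 4.11
  prog$sex <- "M"   # constant response needs no sex term
  vc <- suppressWarnings(suppressMessages(
    estimate_variance_components(prog)))
  ebv <- estimate_ebv(prog, vc)
  expect_true(all(abs(ebv$ebv) < 1e-8))
})

test_that("extreme-group selection takes disjoint tails with a positive differential", {
  set.seed(30)
  ebvs <- data.frame(id = sprintf("I%03d", 1:167), ebv = rnorm(167, 0, 0.1))
  grp <- select_extreme_groups(ebvs, 20)
  expect_length(grp$low, 20)
  expect_length(grp$high, 20)
  expect_length(intersect(grp$low, grp$high), 0)
  expect_gt(mean(ebvs$ebv[ebvs$id %in% grp$high]),
            mean(ebvs$ebv[ebvs$id %in% grp$low]))

  one <- select_extreme_groups(ebvs, 1)
  expect_equal(one$low, ebvs$id[which.min(ebvs$ebv)])
  expect_equal(one$high, ebvs$id[which.max(ebvs$ebv)])
  expect_error(select_extreme_groups(ebvs, 100), "half")
})

test_that("allele and genotype frequencies follow gene counting", {
  g <- c(rep("A/A", 25), rep("A/G", 50), rep("G/G", 25))
  fr <- compute_frequencies(g)
  expect_equal(unname(fr$allele_freqs["A"]), 0.5)
  expect_equal(unname(fr$genotype_freqs[c("A/A", "A/G", "G/G")]),
               c(0.25, 0.5, 0.25))
  expect_equal(sum(fr$allele_freqs), 1, tolerance = 1e-12)
  expect_equal(sum(fr$genotype_freqs), 1, tolerance = 1e-12)

  expect_equal(unname(compute_frequencies(rep("CC", 5))$allele_freqs["C"]), 1)
  expect_error(compute_frequencies(c(NA, NA)), "no called")

  # binomial oracle under Hardy-Weinberg sampling
  set.seed(3)
  g <- rgeno_hwe(10000, 0.3)
  lab <- c("C/C", "C/T", "T/T")[g + 1]
  fr <- compute_frequencies(lab)
  expect_lt(abs(fr$allele_freqs["T"] - 0.3), 0.01)
})

test_that("effect decomposition recovers a planted additive effect", {
  set.seed(44)
  # genotype-independent trait: all codings near zero
  g <- rgeno_hwe(2000, 0.4)
  eff0 <- genotypic_effects(g, rnorm(2000, 4.1, 0.3))
  expect_true(all(abs(eff0$effect) < 0.05))

  # additive truth: slope about 0.1 and additive AIC usually wins
  est <- replicate(20, {
    g <- rgeno_hwe(500, 0.5)
    y <- 4 + 0.1 * g + rnorm(500, 0, 0.3)
    e <- genotypic_effects(g, y)
    c(add = e$effect[e$coding == "additive"],
      win = e$aic[e$coding == "additive"] < e$aic[e$coding == "dominance"])
  })
  expect_lt(abs(mean(est["add", ]) - 0.1), 0.04)
  expect_gte(mean(est["win", ]), 0.8)

  # no alt-homozygotes: recessive coding inestimable
  g <- c(rep(0, 50), rep(1, 50))
  e <- genotypic_effects(g, rnorm(100))
  expect_false(e$estimable[e$coding == "recessive"])
  expect_error(genotypic_effects(rep(1, 50), rnorm(50)), "monomorphic")
})

test_that("genotype-trait ANOVA reduces to the t-test for two groups", {
  set.seed(55)
  g <- rep(c("CC", "CT"), each = 40)
  y <- rnorm(80, 4, 0.3) + 0.1 * (g == "CT")
  an <- genotype_trait_anova(g, y)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p, tt$p.value, tolerance = 1e-9)
})

test_that("Duncan lettering separates a shifted group and stays order-consistent", {
  expect_error(genotype_trait_anova(rep(c("a", "b"), 5), rep(1, 10)),
               "zero residual")
  expect_warning(
    genotype_trait_anova(c(rep("AA", 10), rep("AB", 10), "BB"),
                         rnorm(21)),
    "fewer than 2|< 2")

  set.seed(66)
  distinct <- vapply(1:100, function(i) {
    g <- rep(c("AA", "AB", "BB"), each = 30)
    y <- rnorm(90, rep(c(4.0, 4.0, 4.5), each = 30), 0.2)
    an <- genotype_trait_anova(g, y)
    top <- an$groups[an$groups$genotype == "BB", ]
    others <- an$groups[an$groups$genotype != "BB", ]
    # BB shares no letter with either equal-mean group
    !any(strsplit(top$letters, "")[[1]] %in%
           unlist(strsplit(others$letters, "")))
  }, logical(1))
  expect_gte(mean(distinct), 0.95)

  # groups sharing a letter have no significant pairwise range
  set.seed(67)
  for (i in 1:20) {
    g <- rep(c("AA", "AB", "BB", "CC"), each = 15)
    y <- rnorm(60, rep(c(4, 4.1, 4.2, 4.6), each = 15), 0.25)
    an <- genotype_trait_anova(g, y)
    grp <- an$groups
    for (a in seq_len(nrow(grp) - 1)) {
      for (b in (a + 1):nrow(grp)) {
        shared <- any(strsplit(grp$letters[a], "")[[1]] %in%
                        strsplit(grp$letters[b], "")[[1]])
        if (shared) {
          span <- b - a + 1
          alpha_p <- 1 - 0.95^(span - 1)
          r_h <- nrow(grp) / sum(1 / grp$n)
          lsr <- qtukey(1 - alpha_p, span, an$df[2]) * sqrt(an$mse / r_h)
          expect_lte(grp$mean[a] - grp$mean[b], lsr + 1e-9)
        }
      }
    }
  }
})
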