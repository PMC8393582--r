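sim_geno_trait <- function(n, effects, modes, n_null, noise_sd = 0.3,
                           freq = 0.5) {
  n_causal <- length(effects)
  m <- n_causal + n_null
  G <- matrix(rgeno_hwe(n * m, freq), nrow = n, ncol = m,
              dimnames = list(NULL, sprintf("L%02d", seq_len(m))))
  y <- rep(4, n)
  for (j in seq_len(n_causal)) {
    codes <- switch(modes[j],
                    additive = c(0, 1, 2),
                    dominant = c(0, 1, 1),
                    over_dominant = c(0, 1, 0))
    y <- y + effects[j] * codes[G[, j] + 1]
  }
  list(G = G, y = y + rnorm(n, 0, noise_sd))
}

test_that("single-SNP mode selection identifies the generative gene action", {
  expect_error(fit_single_snp_modes(rep(0, 20), rnorm(20)), "monomorphic")

  set.seed(71)
  pick <- function(mode, effect = 0.3) {
    mean(vapply(1:50, function(i) {
      d <- sim_geno_trait(400, effect, mode, n_null = 0)
      m <- fit_single_snp_modes(d$G[, 1], d$y)
      if (mode == "dominant") {
        m$mode %in% c("dominant_alt", "dominant_ref")
      } else {
        m$mode == mode
      }
    }, logical(1)))
  }
  expect_gte(pick("additive", 0.15), 0.8)
  expect_gte(pick("dominant"), 0.8)
  expect_gte(pick("over_dominant"), 0.8)

  # no genetic effect: the locus usually fails the entry test; choosing
  # the best of four codings inflates the nominal 5% rate, but never
  # beyond the union bound of 4 x 0.05
  null_sig <- mean(vapply(1:100, function(i) {
    g <- rgeno_hwe(200, 0.5)
    fit_single_snp_modes(g, rnorm(200, 4, 0.3))$p < 0.05
  }, logical(1)))
  expect_lte(null_sig, 0.2)
})

test_that("stepwise search recovers planted two-locus networks", {
  set.seed(72)
  hit <- vapply(1:100, function(i) {
    d <- sim_geno_trait(400, c(0.2, 0.2), c("additive", "additive"),
                        n_null = 8)
    s <- stepwise_network_search(d$G, d$y)
    length(s$networks) > 0 &&
      all(c("L01", "L02") %in% s$networks[[1]]$members)
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("networks only form from screen-passing loci around the true signal", {
  set.seed(73)
  for (i in 1:50) {
    d <- sim_geno_trait(400, 0.25, "additive", n_null = 9)
    s <- stepwise_network_search(d$G, d$y)
    members <- unique(unlist(lapply(s$networks, `[[`, "members")))
    # network members are always screen-passing candidates
    expect_true(all(members %in% s$candidates))
    # the true signal always survives the screen
    expect_true("L01" %in% s$candidates)
    # with no null partner past the screen, no size >= 2 network can exist
    if (length(s$candidates) == 1) expect_length(s$networks, 0)
  }
})

test_that("forward and backward searches agree on orthogonal predictors", {
  set.seed(74)
  d <- sim_geno_trait(600, c(0.25, 0.25, 0.2), rep("additive", 3),
                      n_null = 5)
  fw <- stepwise_network_search(d$G, d$y, direction = "forward")
  bw <- stepwise_network_search(d$G, d$y, direction = "backward")
  expect_setequal(fw$selected, bw$selected)
})

test_that("adding a member never lowers training R-squared", {
  set.seed(75)
  d <- sim_geno_trait(300, c(0.25, 0.25, 0.2), rep("additive", 3),
                      n_null = 4)
  s <- stepwise_network_search(d$G, d$y)
  sizes <- vapply(s$networks, function(m) length(m$members), integer(1))
  r2 <- vapply(s$networks, `[[`, numeric(1), "r2")
  for (m in s$networks) {
    larger <- s$networks[vapply(s$networks, function(o) {
      all(m$members %in% o$members) && length(o$members) > length(m$members)
    }, logical(1))]
    for (o in larger) expect_gte(o$r2, m$r2 - 1e-12)
  }
})

test_that("substitution effects convert coefficients to homozygote gaps in grams", {
  set.seed(76)
  d <- sim_geno_trait(500, c(0.15, 0.15), c("additive", "additive"),
                      n_null = 0, noise_sd = 0.2)
  s <- stepwise_network_search(d$G, d$y)
  expect_gt(length(s$networks), 0)
  m <- s$networks[[1]]
  sub <- substitution_effects(m)
  # additive coding: effect = 2 x per-allele coefficient, in grams
  for (l in m$members) {
    if (m$modes[match(l, m$members)] == "additive") {
      expect_equal(sub$substitution_g[sub$locus_id == l],
                   2000 * unname(m$coefficients[l]), tolerance = 1e-9)
    }
  }
  # planted homozygote gap 0.3 kg recovered within 60 g (simulation oracle)
  gaps <- replicate(30, {
    d <- sim_geno_trait(500, 0.15, "additive", n_null = 1, noise_sd = 0.2)
    e <- fit_single_snp_modes(d$G[, 1], d$y)
    codes <- e$codes
    e$effect * (codes[3] - codes[1]) * 1000
  })
  expect_lt(abs(mean(gaps) - 300), 60)

  # orientation flip changes only the sign
  flipped <- fit_single_snp_modes(2 - d$G[, 1], d$y)
  orig <- fit_single_snp_modes(d$G[, 1], d$y)
  expect_equal(abs(flipped$effect * (flipped$codes[3] - flipped$codes[1])),
               abs(orig$effect * (orig$codes[3] - orig$codes[1])),
               tolerance = 1e-9)
})

test_that("over-dominant loci are excluded from substitution reporting by default", {
  set.seed(77)
  d <- sim_geno_trait(600, c(0.25, 0.4), c("additive", "over_dominant"),
                      n_null = 0, noise_sd = 0.2)
  s <- stepwise_network_search(d$G, d$y)
  nets <- Filter(function(m) "L02" %in% m$members &&
                   m$modes[match("L02", m$members)] == "over_dominant",
                 s$networks)
  if (length(nets)) {
    sub <- substitution_effects(nets[[1]])
    expect_true(is.na(sub$substitution_g[sub$locus_id == "L02"]))
    sub2 <- substitution_effects(nets[[1]], include_over_dominant = TRUE)
    expect_equal(sub2$substitution_g[sub2$locus_id == "L02"], 0)
  } else {
    succeed("over-dominant locus not selected in this draw")
  }
})

test_that("Spearman matrices match hand-computed ranks and order columns", {
  x <- 1:5
  m <- cbind(a = x, b = c(2, 1, 4, 3, 5), c = rev(x))
  sp <- spearman_matrix(m)
  expect_equal(sp$rho["a", "a"], 1)
  expect_equal(sp$rho["a", "c"], -1)
  # hand rank formula: 1 - 6*sum(d^2)/(n(n^2-1)), d^2 sums to 4
  expect_equal(sp$rho["a", "b"], 1 - 6 * 4 / (5 * 24))

  expect_warning(sp2 <- spearman_matrix(cbind(a = x, b = rep(1, 5),
                                              c = rev(x))),
                 "constant")
  expect_true(all(is.na(sp2$rho["b", ])))
  expect_error(spearman_matrix(m[1:2, ]), "at least 3")
  expect_s3_class(sp$hclust, "hclust")
  expect_setequal(sp$order, 1:3)
})
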