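# Independent oracles used to freeze or cross-check expected values.
# These deliberately avoid the package's own code paths.

# narrow-sense heritability from a paternal half-sib ANOVA:
# sigma2_sire = (MS_between - MS_within) / k with k the effective
# family size for unbalanced designs; h2 = 4 * sigma2_sire / sigma2_P
halfsib_anova_h2 <- function(sire, y) {
  keep <- !is.na(y)
  sire <- factor(sire[keep])
  y <- y[keep]
  n_i <- tapply(y, sire, length)
  s <- nlevels(sire)
  N <- length(y)
  an <- anova(lm(y ~ sire))
  ms_b <- an[["Mean Sq"]][1]
  ms_w <- an[["Mean Sq"]][2]
  k <- (N - sum(n_i^2) / N) / (s - 1)
  sigma2_s <- max(0, (ms_b - ms_w) / k)
  4 * sigma2_s / (sigma2_s + ms_w)
}

# brute-force Benjamini-Hochberg step-up:
# adj_i = min over { p_j >= p_i } of p_j * m / rank(p_j), capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    candidates <- vapply(seq_len(m), function(j) p[j] * m / r[j], numeric(1))
    min(1, min(candidates[p >= p[i] - 1e-15]))
  }, numeric(1))
}

# multinomial HWE genotype sampler (alt-allele counts)
rgeno_hwe <- function(n, f) {
  stats::rbinom(n, 2L, f)
}

# minimal locus-depth row constructor for hand-built fixtures
depth_record <- function(h, l, ref = "A", alt = "G", q = 30,
                         locus_id = "L1") {
  stopifnot(length(h) == 4, length(l) == 4)
  data.frame(locus_id = locus_id, chrom = "chr1", pos = 1L,
             ref = ref, alt = alt,
             A_H = h[1], C_H = h[2], G_H = h[3], T_H = h[4],
             A_L = l[1], C_L = l[2], G_L = l[3], T_L = l[4],
             Q = q, stringsAsFactors = FALSE)
}

# small default population used by several tests
small_config <- function(seed = 1, ...) {
  simulation_config(n_sires = 5, dams_per_sire = 3, progeny_per_dam = 4,
                    n_loci = 40, n_causal = 2, seed = seed, ...)
}
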