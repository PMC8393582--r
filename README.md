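# bulkseg

Bulked segregant analysis (BSA) and sib-based breeding-value pipelines for
pooled SNP data in outbred populations.

`bulkseg` is aimed at animal-breeding and population-genetics researchers
who map quantitative-trait loci by sequencing pooled DNA from phenotypic
extremes — the SLAF-/RAD-style reduced-representation BSA design used for
body-weight traits in poultry and waterfowl. It implements the full
computational chain of such a study, and a synthetic-data generator that
emulates the study population, so every stage is testable without any
sequencing data.

## What it computes

**Pooled-bulk locus statistics.** Per locus, base depths of the high- and
low-EBV bulks are normalised to fractions and compared by the Euclidean
distance

    ED = sqrt( Σ_b (f_b,H − f_b,L)² ),   b ∈ {A, C, G, T}

(for a biallelic locus ED = √2·|Δ allele frequency|), by the per-bulk SNP
index M/(M+P) (alternative-allele read fraction) and its between-bulk
difference Δ(SNP index), and by the Phred quality Q = −10·log₁₀(p_err).
The joint screen ED ≥ 0.7, |Δ(SNP index)| ≥ 0.5, Q ≥ 30 (inclusive)
selects differentiated loci.

**Bulk association.** Pearson chi-square on the 2×2 bulk × allele depth
table per locus, Benjamini–Hochberg and Bonferroni control at 5%, and
staged candidate selection (family-wise hits, or the top-k shortlist
carried into individual genotyping).

**Quantitative genetics.** Nested sire/dam REML variance components
(`lme4`), σ²A = 4σ²sire, and breeding values by parent average plus the
within-family deviation shrunken by h²w = ½σ²A/σ²e; extreme-group
selection; Shapiro–Wilk trait checks; one-way genotype–trait ANOVA with
Duncan multiple-range letters; allele/genotype frequencies; and
additive (0,1,2) / dominance (0,1,1) / recessive (0,0,1) effect
regressions.

**SNP networks.** Per-locus gene-action mode selection by AIC (additive,
dominant, over-dominant codings), stepwise multi-marker regression with
entry/stay p < 0.05, enumeration of all jointly significant networks of
2–4 loci ranked by AIC, homozygote substitution effects in grams, and
Spearman correlation matrices with clustering order for heat maps.

**Expression.** Relative quantification by 2^−ΔΔCT against a calibrator
genotype group and two-tailed t-tests between groups (on log₂ RQ by
default).

## Worked example

A complete synthetic study — simulate a sib-structured population
(8 sires × 5 dams × 8 progeny, h² = 0.29, five causal loci), estimate
EBVs, pool the 20 highest and lowest males, sequence the pools in
silico at 25×, and run the screen:

```r
library(bulkseg)

cfg <- pipeline_config(simulation_config(n_loci = 400, seed = 42),
                       out_dir = "bulkseg-run")
run <- run_pipeline(cfg, quiet = TRUE)
print(run)
#> BSA pipeline run
#>   simulate: 320 progeny, 400 loci (5 causal)
#>   ebv: h2 = 0.279, h2_w = 0.154 over 320 phenotyped individuals
#>   ebv: selected 2 x 20 extreme males from 165
#>   score: 400 loci in, 23 pass filter, 377 rejected
#>   test: 23 loci tested, 23 Bonferroni hits, top-23 shortlist
#>   assoc: 10 candidate loci profiled (10 with valid ANOVA)
#>   networks: 7 candidates -> 2 selected -> 1 networks
#>   express: fold 1.50 planted, mean RQ 1.439 recovered, p = 0.000227
#>   bundle: bulkseg-run
```

The recovered heritability (0.279) sits at the configured 0.29 within
sampling error, and the top-ranked candidate locus is one of the five
planted causal loci (`run$population$loci` carries the truth). Each
profiled candidate gets an ANOVA with Duncan letters and an effect
decomposition:

```r
run$candidate_reports[[1]]$anova
#> One-way ANOVA: F(2, 162) = 14.351, p = 1.828e-06
#>  genotype  n     mean         se letters
#>   alt_hom 40 4.463527 0.06089831       a
#>       het 68 4.208837 0.04849399       b
#>   ref_hom 57 4.032582 0.05049583       c

run$candidate_reports[[1]]$effects
#>      coding    effect         se            p       aic estimable
#> 1  additive 0.2125878 0.03988596 3.228854e-07 -309.3628      TRUE
#> 2 dominance 0.2705848 0.06572768 6.090434e-05 -299.1757      TRUE
#> 3 recessive 0.3350619 0.07199458 6.707516e-06 -303.4406      TRUE
```

Here the additive coding wins on AIC and its slope (0.21 kg per allele
copy) corresponds to a homozygote substitution effect of ~430 g. The
run directory contains the phenotype/pedigree CSV, genotype TSV, scored
locus TSV, association TSV, network JSON, Spearman matrix and expression
tables, each with seed and config hash in its header; identically seeded
runs are byte-identical.

A thin command-line wrapper over the same functions ships at
`inst/cli/bsa.R`:

```sh
Rscript inst/cli/bsa.R run --seed 42 --out-dir bulkseg-run
Rscript inst/cli/bsa.R score --in depths.tsv --out scored.tsv --ed-min 0.7
```

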