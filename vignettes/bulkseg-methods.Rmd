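---
title: "Methods: pooled-bulk marker discovery and sib-based breeding values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-bulk marker discovery and sib-based breeding values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkseg)
```

## The study design this package implements

`bulkseg` implements the computational chain of a bulked-segregant
analysis (BSA) of a quantitative trait in an outbred sib-structured
population — the design used to map body-weight loci in poultry and
waterfowl with reduced-representation pooled sequencing:

1. phenotype a population with known sire/dam pedigree; check the trait
   for normality;
2. predict each individual's breeding value (EBV) from full- and
   half-sib information; pool DNA from the highest- and lowest-EBV
   individuals into two bulks;
3. sequence both pools, and per biallelic locus compare the bulks' base
   compositions (Euclidean distance, SNP index) under a joint quality
   filter;
4. test allele-frequency contrasts between bulks by chi-square with
   false-discovery-rate and Bonferroni control, and carry a shortlist of
   top-ranked loci into individual genotyping;
5. associate candidate genotypes with the trait (one-way ANOVA, Duncan
   mean separation, additive/dominance/recessive decomposition);
6. combine markers into multi-SNP regression models ("SNP networks")
   with per-locus gene-action codings and homozygote substitution
   effects;
7. compare relative expression of nearby genes between genotype groups
   by the 2^−ΔΔCT method.

Every stage is driven by a synthetic-data generator, so the whole chain
can be exercised and validated without sequencing data.

## Pooled-bulk statistics

For a locus with per-base read depths $(A, C, G, T)$ in each bulk, the
depths are first normalised to within-bulk fractions and the Euclidean
distance between the two fraction 4-vectors is

$$\mathrm{ED} = \sqrt{\sum_{b \in \{A,C,G,T\}} (f_{b,H} - f_{b,L})^2},$$

which for a biallelic locus equals $\sqrt{2}\,|\Delta f|$ with
$\Delta f$ the allele-frequency difference, so $\mathrm{ED} \in
[0, \sqrt 2]$. Working on fractions rather than raw depths is the only
reading under which reported ED values of screening studies (0.7–1.1)
are attainable, since raw-depth distances scale with coverage.

The SNP index of a bulk is $M/(M+P)$, the fraction of reads carrying
the focal (alternative) allele; $\Delta(\text{SNP index})$ is the
high-bulk minus low-bulk index. In an outbred population there is no
parental-origin labelling of alleles, so the package fixes $M$ = the
alternative allele and $P$ = the reference allele and records the
orientation per locus. A locus passes the screen when jointly
$\mathrm{ED} \ge 0.7$, $|\Delta(\text{SNP index})| \ge 0.5$ and the
Phred quality $Q = -10\log_{10} p_{\mathrm{err}} \ge 30$ (all
inclusive). The filter is applied to the *absolute* index difference:
a signed per-bulk threshold would not separate bulks, and the screening
rule is about segregating differences. Multi-allelic records are scored
on the declared ref/alt pair (or the two most abundant bases when no
pair is declared); minor bases still contribute to ED through the full
4-vector but not to the SNP index.

Allele-frequency contrasts are tested per locus by the Pearson
chi-square statistic on the 2×2 bulk-by-allele depth table (1 df, no
continuity correction — expected counts at 25× depth are large).
Adjustment uses Benjamini–Hochberg (FDR) and Bonferroni at a 5% overall
type-I level; candidate selection offers both the family-wise rule
(`p_bonf < 0.05`) and a fixed-size top-*k* shortlist (default 31, the
shortlist size such screens carry into individual genotyping).
Ranking ties are broken by locus id for determinism. Allele counts come
from pooled read depths directly, not from imputed per-individual allele
counts; a depth-based test is what pooled data support, and the
config exposes the alternative nowhere because the raw allele counts of
the bulked individuals are available in the synthetic truth anyway.

## Breeding values from sib structure

Variance components come from the nested random-intercept model
`mw ~ (1 | sire) + (1 | sire:dam)` fitted by REML (`lme4`), plus a
fixed sex effect when both sexes are present. The sire component
estimates $\tfrac14 \sigma^2_A$ (paternal half-sib covariance), so
$\hat\sigma^2_A = 4\hat\sigma^2_{\text{sire}}$; the dam-within-sire
component is left out of that conversion because full-sib covariance is
contaminated by dominance and common environment. Heritability is
$\hat h^2 = \hat\sigma^2_A / \hat\sigma^2_P$, clipped to $[0,1]$.

Individual EBVs follow the parent-average-plus-Mendelian-deviation
decomposition
$$\hat a_{ijk} = \tfrac12(\hat a_j + \hat a_k) + \hat w_{ijk}, \qquad
  \hat w_{ijk} = h^2_w\, e_{ijk},$$
where parental values are twice the sire and dam BLUPs of the fitted
model (so the parent average is exactly the model's random-effect
contribution for the family) and $e_{ijk}$ is the individual's model
residual. The within-family heritability is implemented exactly as
$h^2_w = \tfrac12 \sigma^2_A / \sigma^2_e$, with the model residual
variance in the denominator; this is unusual (the textbook shrinkage
uses within-family phenotypic variance) but it is the printed
definition this pipeline reproduces, and
`estimate_variance_components(h2w_definition = "phenotypic")` offers
the textbook alternative. Individuals without parent links are treated
as founders with parent-average 0, shrinking their deviation from the
fixed-effect prediction. Extreme bulks are the bottom and top
`n_per_tail` individuals by EBV (ties broken by id).

## Genotype–trait association and effect decomposition

Per-locus association uses one-way ANOVA over genotype classes with at
least two observations (smaller classes are dropped with a warning).
Mean separation uses Duncan's multiple range test, implemented from the
studentized-range definition: for a span of $p$ ordered means the least
significant range is $R_p = q(1-\alpha_p,\, p,\, \mathrm{df}_e)
\sqrt{\mathrm{MSE}/r_h}$ with protection level $\alpha_p = 1 -
(1-\alpha)^{p-1}$ and $r_h$ the harmonic mean class size; maximal
ranges whose extreme pair is below $R_p$ share a letter. No installed
package provides Duncan's test, so it is implemented here and
property-tested for order-consistency (groups sharing a letter never
have a significant pairwise range at the protected level).

The additive/dominance/recessive decomposition fits three separate
single-predictor regressions of the trait on alternative-allele codings
across {ref-hom, het, alt-hom}: additive $(0,1,2)$ (slope = effect per
allele copy, kg), dominance $(0,1,1)$, recessive $(0,0,1)$. The source
study does not state its codings; these are the standard choices and
are documented in the output. Model quality is reported as the
constant-free AIC $n\ln(\mathrm{RSS}/n) + 2k$ ($k$ = number of
regression coefficients); only AIC differences between models of the
same response are meaningful, and absolute AIC values of other software
are not comparable.

## SNP networks

Each locus first gets a gene-action mode by AIC over four codings:
additive $(0,1,2)$, dominant towards either homozygote $(0,1,1)$ /
$(0,0,1)$, over-dominant $(0,1,0)$; AIC ties resolve to the simpler
interpretation (additive, then dominant, then over-dominant). Loci with
single-SNP $p < 0.05$ on their best coding enter a stepwise search
(forward or backward) with entry/stay threshold 0.05 on partial
F-tests, capped at four members. Because the original multi-marker
protocol enumerates named networks without disclosing its traversal,
`bulkseg` enumerates *all* subsets of the stepwise-surviving loci of
size 2–4 whose members remain jointly significant, ranked by AIC; this
reproduces the "types of networks" structure (four-, three- and
two-SNP networks) without guessing a traversal order. Collinear codings
drop the later-entering locus with a warning.

The homozygote substitution effect of a member locus is the
model-predicted trait change when one homozygote class replaces the
other, holding other members fixed: coefficient × (alt-hom code −
ref-hom code), reported in grams. For additive codings this is twice
the per-allele coefficient. Over-dominant loci have identical
homozygote codes; their substitution effect is excluded from reporting
by default because it is not a usable selection quantity.

Mode selection is a best-of-four model choice, so a truly null locus
passes the single-SNP screen more often than the nominal 5% (about
10–12% empirically; bounded by 4 × 5%). With ~10 candidate loci this
makes occasional spurious two-locus networks expected rather than
exceptional; the tests therefore assert the structural guarantees
(members always pass the screen; no network forms without a second
screen-passing locus) and the power property (two planted causal loci
are recovered as the top network in ≥ 80% of replicates), not a
near-zero false-network rate the procedure cannot deliver.

Spearman matrices use midrank ties and pairwise-complete observations;
the heat-map display order comes from average-linkage clustering of
$1 - |\rho|$. Constant columns yield `NA` with a warning.

## Relative expression

Technical replicates are averaged within biological sample before any
statistic; $\Delta CT$ is target minus reference CT,
$\Delta\Delta CT$ subtracts the calibrator group's mean $\Delta CT$
(the reference-homozygote group by default, since the source protocol
does not name its calibrator), and $RQ = 2^{-\Delta\Delta CT}$. Group
comparisons use a two-tailed t-test on $\log_2 RQ = -\Delta\Delta CT$
by default: under Gaussian CT noise, RQ is log-normal, so the log scale
matches the error model (`scale = "rq"` tests raw RQ instead).

## What the synthetic generator emulates — and what it does not

`simulation_config()` defaults define the reference study conditions:

| parameter | default | rationale |
|---|---|---|
| heritability | 0.29 | narrow-sense h² of marketing weight in the emulated study |
| trait_mean | 4.11 kg | male marketing weight at nine weeks |
| trait_sd | 0.45 kg | CV ≈ 11%, realistic for gosling body weight |
| sex_effect | 0.61 kg | male-minus-female mean difference (4.11 vs 3.50 kg) |
| pedigree | 8 sires × 5 dams × 8 progeny | ~320 goslings (~160 males), matching the 167-male study scale; 1:5 mating ratio typical of commercial geese; few, large sire families reproduce the strong between-family allele-frequency drift that pooled extreme bulks of such populations show |
| n_causal, effects | 5 loci × 0.15 kg/allele | the largest effect at which five loci's analytic additive variance stays within the h²·σ²P budget — a major-gene architecture, which is the regime a 20+20-bulk screen is powered for |
| bulk_size | 20 | individuals per extreme-EBV pool |
| mean_depth_per_bulk | 25 reads | per-bulk pooled coverage of the emulated screen (~45× combined) |
| sequencing_error_rate | 0.001 | Phred 30 |

Phenotypes decompose as mean + sex offset + causal genotypic value +
polygenic breeding value + environment. Causal loci contribute their
analytic additive variance ($2pq\alpha^2$ per locus, $\alpha$ the
average substitution effect); a polygenic term (parent average +
Mendelian sampling) absorbs the remaining additive variance so that
narrow-sense heritability matches the configuration; dominance
deviations of non-additive modes ride on top and count as neither
additive nor environmental. Pooled depths are Poisson totals with
multinomial base counts at the bulk's true allele frequency, the
standard pooled-sequencing model; sequencing errors redistribute
probability uniformly over the other three bases.

Deliberately not simulated: linkage and LD between loci (loci are
independent, so the chromosome-trimming use of networks cannot be
reproduced, only their statistical construction), genotype×sex
interaction, read-level artefacts (duplicates, mapping bias),
restriction-site dropout, and family-correlated environments. Passing
tests therefore validate the *statistical machinery* under a clean
generative model, not robustness to those real-data features.

## Numerical choices and degenerate inputs

- All randomness flows from one integer seed; child streams are derived
  per stage by a fixed hash, so identically seeded runs are
  byte-identical (`run_pipeline` writes seed and a config hash into
  every output header).
- Zero total depth in a bulk makes ED undefined (error); zero depth on
  both focal bases makes the SNP index `NA` and the locus unfilterable.
- An error rate of 0 yields infinite quality, which survives the TSV
  round trip.
- Constant traits: normality check and ANOVA raise degenerate-input
  errors; constant phenotypes give zero EBVs via a singular (zero
  variance) model fit.
- Tables are written with 17 significant digits and a forced decimal
  point so write-then-read reproduces doubles, integers and `NA`
  markers exactly.
- Monomorphic loci are inestimable for effects/modes (error), and
  monomorphic columns in the association screen carry a not-testable
  flag rather than a p-value.

## Problem sizes used by the test suite

The suite validates the heavy properties at deliberately modest sizes:
heritability recovery uses 50 replicates of a 100-sire × 5-dam ×
8-progeny population; network recovery uses 100 replicates of n = 400
with 10 loci; the chi-square null calibration uses 2000 replicate
tables; end-to-end candidate recovery uses 20 seeded runs of the
default population with 150–400 loci. These sizes keep each property's
Monte-Carlo error comfortably inside the asserted bounds.

## Known limitations

- The nested sire/dam REML model is a stand-in for the unpublished
  evaluation model of the emulated study; with very few sires the sire
  variance (hence h² and EBV accuracy) is estimated with large error.
- $h^2_w$ with residual-variance denominator can exceed 1 for high
  heritabilities; it is applied as printed, not clipped.
- The stepwise search is exhaustive over subsets of the selected loci
  only (≤ 4 members), not over all candidate subsets.
- Duncan lettering uses the harmonic mean class size, the usual
  approximation for unbalanced classes.
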