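---
title: "Sex-limitation twin modeling and mixed-model association for serum uric acid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-limitation twin modeling and mixed-model association for serum uric acid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsua)
```

## The scientific problem

Serum uric acid (SUA, µmol/L) is the end product of purine metabolism and
a risk marker for gout, kidney disease and cardiometabolic disorders. Two
questions drive the workflow implemented here: *how much of the variation
in SUA is genetic, and does that differ between women and men?* (answered
with the classical twin design), and *which common variants track SUA?*
(answered with a mixed-model genome-wide scan and its gene-level
aggregations). The package reproduces the full analysis stack of a
379-pair middle/old-aged twin cohort — 240 monozygotic (MZ) pairs and 139
dizygotic (DZ) pairs in five zygosity-sex groups, with genotypes for the
DZ pairs — on synthetic cohorts that share the statistical structure of
the original data, which are not redistributable.

## The sex-limitation ACE model

The phenotype of a twin is decomposed into additive genetic (A), common
or shared environmental (C) and unique environmental (E) deviations, with
path coefficients allowed to differ by sex:

- female variance: $a_f^2 + c_f^2 + e_f^2$
- male variance: $a_m^2 + a_{m'}^2 + c_m^2 + e_m^2$, where $a_{m'}$ is a
  male-specific additive genetic factor with no female counterpart.

Expected within-pair covariances follow from the biometric rules — A
correlates 1 in MZ and 0.5 in DZ pairs, C correlates 1 in every pair, E
is independent:

| group | covariance |
|---|---|
| MZ female | $a_f^2 + c_f^2$ |
| MZ male | $a_m^2 + a_{m'}^2 + c_m^2$ |
| DZ female | $\tfrac12 a_f^2 + c_f^2$ |
| DZ male | $\tfrac12 a_m^2 + \tfrac12 a_{m'}^2 + c_m^2$ |
| DZ opposite-sex | $\tfrac12 a_f a_m + c_f c_m$ |

The male-specific factor contributes nothing to the opposite-sex
covariance — that asymmetry is what identifies it. Opposite-sex pairs are
stored female-first throughout so the 2×2 covariance has a fixed
orientation.

The model ladder mirrors the published analysis: Model I frees all seven
paths; II drops $a_{m'}$; III additionally drops $c_m$; IV drops $c_f$;
V and VI are the cross-sex-equal AE and ACE models. We implement the
"scalar" models V/VI as strict equality of paths because that is the
parameter count the published degrees of freedom imply; a literal
scalar-multiplier variant (`model_spec(..., scalar = TRUE)`) is provided
but adds a parameter and does not match those df.

### FIML and its numerical treatment

Fitting is full-information maximum likelihood: each pair contributes
minus twice the log of a bivariate normal density with its group's
model-implied covariance and per-twin means that are linear in
covariates (definition-variable style). The default means design has
five coefficients — female and male intercepts, centered age, centered
BMI, and an age-by-male interaction — because five mean parameters
reproduce the published df bookkeeping (12/11/10/9/7/8 free parameters
for Models I–VI at 379 pairs give df 746/747/748/749/751/750). The
design is an argument, and df is always recomputed from the design
actually used.

Because the covariance is constant within a group and means are linear,
the likelihood depends on the data only through per-group cross-products;
`fit_model()` precomputes them once, profiles the mean coefficients by
generalized least squares at every covariance evaluation, and optimizes
only the variance paths (bounded at zero, `e > 0`), so a fit costs the
same at 379 pairs or 25,000 pairs. Optimization uses `nlminb` with ten
restarts (an equal-split start, a Falconer-style start derived from the
observed MZ/DZ correlations, and Latin-hypercube draws over the share
simplex), followed by a tight polishing pass; non-positive-definite
covariances act as a barrier. Convergence diagnostics (restart count,
numerical gradient norm) are attached to every fit.

Model choice follows the published rule: a sub-model is rejected when
its likelihood-ratio test against its declared parent is significant at
0.05; among the general model and unrejected sub-models the lowest AIC
wins, with AIC in the Mx convention $-2LL - 2\,df$ (the convention that
reproduces every published AIC from its -2LL/df pair; the textbook
$-2LL + 2k$ is available but unused for that comparison).

Confidence intervals for standardized components are profile-likelihood
intervals: the set of share values whose constrained $-2LL$ lies within
3.84 of the minimum. The constrained sex block is reparameterized as
(total SD, share splits) so the target share is held exactly; the
profile is bracketed on a coarse grid from the estimate outward and
refined by bisection with warm starts, and bounds are clipped to
[0, 100] — estimates at the boundary report a bound of exactly 0, as in
the published table.

## Phenotype preparation

Exclusions are pairwise (gout, systemic lupus erythematosus, eGFR < 60%,
creatinine > 1.4 mg/dL, or a missing phenotype in either twin removes
the pair) and logged with reason codes. Normalization uses the Blom
rank-based inverse-normal transform
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, applied to the whole retained
sample with average ranks for ties; sex differences are then handled in
the means model. The order is exclusions → Blom → modeling; for the
descriptive twin correlations a pre-residualization on age, sex and BMI
(`adjust_covariates()`) replicates the published "after adjusting"
correlations, while the FIML stage keeps covariates in the means — both
paths are exposed because the published text does not fix the order.
Twin correlations are single-entry Pearson coefficients with Fisher-z
intervals using $SE = 1/\sqrt{n-3}$; this exactly reproduces the
published MZ interval (0.47–0.64 at r = 0.56, n = 240), while the
published DZ interval (0.25–0.50 at r = 0.39, n = 139) differs in the
last digit from the Fisher-z value (0.24–0.52) and is deliberately not
forced.

## The association stack

SNP quality control keeps a marker iff call rate ≥ 0.98, missingness ≤
0.05 (both applied literally despite their overlap), Hardy–Weinberg
exact p ≥ 1e-4 and MAF ≥ 0.05, with MAF computed on non-missing calls
after minor-allele orientation. The HWE test is the exact conditional
(Levene–Haldane) test computed with log-factorials; with twin data it
uses one randomly chosen twin per pair (fixed seed) so within-pair
dependence does not inflate it.

Association uses a single-random-effect mixed model
$y = W\alpha + x\beta + u + \varepsilon$, $\mathrm{cov}(u) =
\sigma_g^2 K$, with $K$ the centered-and-scaled GRM. $K$ is
eigendecomposed once and the variance ratio
$\lambda_g = \sigma_g^2/\sigma_e^2$ is profiled on the null model by a
one-dimensional search of $\log_{10}\lambda_g \in [-5, 5]$; each SNP is
then a GLS Wald test with the fitted weights. The profile uses REML by
default: with a centered GRM the constant vector is a null-space
direction fitted exactly by the intercept, and the plain-ML profile
degenerates there ($\hat\sigma_e^2 \to 0$ as $\lambda_g \to \infty$);
REML's determinant term penalizes exactly that collapse. An ML switch
remains, guarded by an interior-local-minimum grid scan for multimodal
profiles. Genomic control is $\lambda = \mathrm{median}(\chi^2_{Wald}) /
0.4549$, reported to two decimals; hits are classified at the
conventional 5e-8 (genome-wide) and 1e-5 (suggestive) thresholds.

Gene-based tests aggregate the 1-df chi-square quantiles of member-SNP
p-values and simulate the null by multivariate normal draws under the
local LD correlation (ridge 1e-6), with the +1-corrected empirical
p-value and adaptive escalation of the simulation count (1e4 → 1e6 when
p < 1e-3) — a fixed-count analogue of adaptive gene-based testing, not a
claim of numerical parity with any specific tool. LD is estimated from
the cohort's own genotypes (one twin per pair); the correlation matrix
is injectable for external panels. The per-gene threshold is
0.05/n_genes (2.63e-6 at the published count of 19,001 genes).
Over-representation of a query gene list is the hypergeometric upper
tail on set-within-universe overlaps with Benjamini–Hochberg FDR; the
universe defaults to all genes with at least one assigned SNP, so
published enrichment p-values (whose universe is not recoverable) are
matched only through their k/K bookkeeping.

## The synthetic cohort generator

`simulate_twin_cohort()` draws the five groups at the published sizes by
default (114/126 MZ male/female, 41/39/59 DZ male/female/opposite-sex)
with phenotype `means(covariates) + sd · (a·A + c·C + e·E [+ am'·Am'])`,
factors shared exactly as the model assumes. Generator defaults were
chosen once to echo the published marginals: age uniform on 41–69 years
(the published 95% range), shared within pair; BMI Normal(24.5, 3.2²)
per twin; sex-specific SUA intercepts 226 and 298 µmol/L with residual
scale 55 µmol/L, matching the published medians and approximate 95%
ranges; modest linear covariate effects (0.8 µmol/L/year, 3 µmol/L per
BMI unit, 0.4 µmol/L/year extra in males). Exclusion-flag rates default
to zero so cohorts of a requested size are exact; the analysis scripts
turn them on to exercise the exclusion stage. DZ genotypes come from
explicit parental allele draws with independent meiosis per sibling, so
identity-by-descent sharing is 0/1/2 with probabilities ¼/½/¼ by
construction; MAFs are uniform on a requested range and missingness is
independent per entry.

What the generator deliberately does **not** emulate: linkage
disequilibrium blocks, population stratification, assortative mating,
X-linked effects, batch-structured missingness, or non-normal phenotype
tails. Passing tests therefore certify the estimators against the
model's own assumptions — parameter recovery, calibration of null
distributions, df bookkeeping — not robustness to real-data violations
of them.

## Problem sizes and numerical defaults

The test-suite and acceptance computations use sizes chosen for
precision per CPU-second: parameter recovery at 5,000 pairs per group
(the Monte-Carlo SE of a recovered share is then well under one
percentage point of its ±3-point criterion), the null association scan
at 200 DZ pairs × 5,000 SNPs, gene-test calibration at 1e4–1e5 null
draws, and profile-CI coverage at 120/120/60/60/60 pairs over 20
replicates. Optimizer tolerance is 1e-8 relative on −2LL with a 1e-14
polishing pass; LRT statistics that are negative by less than 1e-6 are
treated as 0 and larger negatives raise a convergence error; Blom
scores of tied values use average ranks; empirical gene p-values are
never 0 by the +1 correction.

## Known limitations

Raw individual-level data behind the published fits are unavailable, so
the published −2LL values themselves cannot be recomputed — only the
arithmetic derived from them (AIC, LRT, model choice) and the behavior
of the estimators on cohorts generated under the published parameter
values. ADE/dominance models, X-chromosome dosage, imputation and
multi-component variance models are out of scope. The means design of
the original analysis is identified only up to its parameter count
(five); which fifth covariate term was used is declared, not inferred.
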