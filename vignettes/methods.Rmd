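---
title: "Models and methods: preharvest sprouting, germination dynamics and malting quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maltgerm)
```

# The scientific problem

Preharvest sprouting (PHS) — germination of mature grain on the spike after
rain — destroys malting value, so malting barley breeders select against it.
Dormancy at harvest, however, is genetically entangled with the enzymatic
quality of the malt: the HvMKK3 dormancy locus (alleles D = dormant,
N = non-dormant, N* = highly non-dormant and PHS-susceptible) appears to act
pleiotropically on traits such as alpha amylase (AA) and free amino nitrogen
(FAN). This package implements the quantitative-genetic analysis chain used
to study that entanglement in a spring barley breeding population: germination
statistics over after-ripening time, variance partitioning of malting assays,
heritability, line BLUEs, bivariate genetic correlations across and within
HvMKK3 allele groups, correlated response to selection, and end-use quality
scoring — together with a synthetic breeding-population generator that gives
every stage a ground truth to be validated against.

# Germination statistics

A germination assay plates 30 kernels and counts germinated kernels at 24,
48 and 72 h. Germination percentage is GE = (n24 + n48 + n72) / n_plated, and
the germination index

GI = 10 (n24 + n48 + n72) GE / (1 n24 + 2 n48 + 3 n72)

is an inverse-mean-germination-time rate on [0, 10]: 10 means every plated
kernel germinated within a day, 0 means nothing germinated. The 0/0 case (no
germination) is defined as GI = 0, the dormant extreme, consistent with low
GI indicating PHS resistance. Technical plate replicates (two per plot) are
averaged per plate *after* computing the index, not by pooling counts.
Assays are run at seven after-ripening timepoints TP1..TP7 (6, 20, 34, 48,
69, 110, 160 days post physiological maturity); GI at TP1 is the PHS
resistance measure and is exposed as `phs_score()`.

# The REML engine

All mixed models in the package are fitted by a purpose-built restricted
maximum likelihood engine (`fit_lmm()`) for the Gaussian family actually
needed here: arbitrary fixed factorial terms; independent random terms with
IID, per-stratum (diagonal) or unstructured 2x2 covariance; and IID or
per-stratum residual variance. The restricted likelihood is evaluated
through the mixed-model equations with a sparse Cholesky factorisation whose
symbolic analysis is reused across evaluations. One overall scale is
profiled out analytically, remaining variances are optimised as log ratios,
and the 2x2 structure is parameterised by its Cholesky factor so estimates
stay positive semi-definite. Optimisation uses the PORT routines (`nlminb`)
from three deterministic starting points (plus, in nested likelihood-ratio
comparisons, a warm start at the reduced model's optimum, which guarantees
the full model is never under-optimised relative to its null). Convergence
is declared at a relative tolerance of 1e-12 on the deviance; hitting the
iteration limit flags the fit as non-converged rather than failing silently.

Numerical choices worth knowing about:

* The response is centred internally when an intercept is present, making
  shift invariance exact in floating point.
* Aliased fixed-effect columns are dropped via a rank-revealing QR and
  reported; Wald tables list them with `aliased = TRUE` and no test.
* Degrees of freedom for Wald t statistics default to the residual
  approximation n − rank(X) (a `containment` option subtracts the random
  levels). Exact small-sample (Kenward–Roger type) degrees of freedom for
  heterogeneous structures are out of scope; the simulation studies in the
  test suite use effect sizes for which the df choice is immaterial.
* Likelihood-ratio tests are only allowed between fits with identical fixed
  structures (REML likelihoods are otherwise incomparable) and the statistic
  is clipped at zero. A genetic correlation of zero is an interior point, so
  the df = 1 chi-square reference is calibrated; the variance-homogeneity
  test across selection cycles uses df = cycles − 1 and is approximate near
  the zero-variance boundary.
* On balanced designs the engine reproduces method-of-moments ANOVA closed
  forms to 1e-6 and matches an independent implementation (lme4) to ~1e-7 in
  restricted log-likelihood; both are enforced in the test suite.

# Variance partitioning and heritability

Per trait, year and malting timepoint, the technical repeatability model
(random plot, residual assay error) gives the assay's "technical
heritability" sigma2_pl / (sigma2_pl + sigma2_e). Within year, the model
Y = TP + line + line:TP + e splits the line-by-timepoint variance
sigma2_gTP, which confounds genuine after-ripening change in the trait with
plot-level sampling error (a small grain sample is drawn from the plot for
each malting). The replicated check cultivar — grain from one lot inserted
every 15 malting samples — carries no genetic variance, so the variance of
its per-plot means minus the scaled assay error estimates the plot-level
error sigma2_pltE, and

sigma2_dgTP = sigma2_gTP − sigma2_pltE

is the after-ripening change variance, reported with ratio1 =
sigma2_pltE / sigma2_gTP and ratio2 = sigma2_dgTP / sigma2_g. Negative
sigma2_dgTP (plot error exceeding the interaction variance) is flagged and
reported as-is, never truncated — it is informative about assay resolution.
Check plot means are centred within year and malting timepoint before taking
their variance, since those shifts are fixed effects, not plot error. The
check variance is computed on per-plot means with the assay error scaled by
the technical replicate count, because sigma2_pltE is defined at plot level.

Across years, Y = year + TP + year:TP (fixed) + line + line:TP + e yields
across-year heritability on a line-mean basis

H2 = sigma2_g / (sigma2_g + sigma2_gTP + sigma2_e / y),

with y the number of years. The per-year variant divides by the full
residual (y = 1); that form is this package's labelled assumption, as only
the across-year formula is standard. Late-malted material without rigid
after-ripening control is merged into across-year fits under the TP6 label
(`assign_tp6()`), because trait change beyond ~110 days post maturity is
below assay resolution.

# Line BLUEs

Three fixed-effect reparameterisations produce line means for downstream
association analysis: per-timepoint cell means; across timepoints within a
year (Y = TP + line, timepoints treated as replicates); and across years
with a separate residual variance per year estimated by REML on the residual
layer (feasible GLS), so noisier years are down-weighted. Line effects are
reported as adjusted means — the line effect plus the average of the fixed
covariate effects over the observed grid — so the schemes are comparable. A
line absent at a timepoint yields no imputed entry; a line seen at only one
timepoint is adjusted by the timepoint contrast estimated from the others.
Note that with *estimated* heterogeneous weights the balanced-data fit does
not reduce exactly to simple means (the weight ratio carries sampling error
of order sqrt(2/df)); `weights = "homogeneous"` restores the exact
reduction.

# Genetic correlations and the HvMKK3 stratification

For a malting trait and a germination trait, plot-level means (technical
replicates averaged; malting timepoints averaged per plot) are stacked into
the bivariate model with fixed trait-by-year cell means, a line effect with
unstructured 2x2 covariance across traits, and heterogeneous residual
variance per trait-year cell. Residual cross-trait covariance is fixed at
zero: the two traits are measured on different grain samples from the plot,
and with mostly one plot per line it is near-unidentifiable anyway. The
genetic correlation r_g = cov / sqrt(v_A v_B) is tested against the diagonal
model by a df = 1 likelihood-ratio test; the scan over timepoints and
HvMKK3 groups stars results at p < 0.01. Boundary estimates (|r_g| > 0.999)
are reported and flagged rather than suppressed. Groups under 30 lines are
fitted but flagged `low_n`.

HvMKK3 alleles are classified from two diagnostic markers: the E165Q
mutation defines N*; among E165Q wild types a linked 50k-chip marker
separates N from D. Because the physical allele coding of the linked marker
is array-batch dependent, the mapping is configurable
(default A -> N, B -> D); any missing call yields UNKNOWN, which excludes
the line from within-allele analyses only.

Phenotypic trait relationships use Pearson correlations of scaled, centred
BLUEs on pairwise-complete lines (casewise deletion would discard most
lines, since availability differs across years), followed by an
eigen-decomposition for biplots; small negative eigenvalues from pairwise
completion are clipped at zero with a warning.

# Correlated response to selection

Per trait, Y = year + cycle + TP + year:TP + TP:cycle + year:cycle (fixed)
+ line + e, with a separate genetic variance per selection cycle (diagonal
structure on the line effect) and a separate residual variance per year.
Cycle effects are contrasts against the C0 base population, tested by Wald
t; the heterogeneous-variance model is compared with its homogeneous
counterpart by an LRT on cycles − 1 df. Interaction terms whose cycle-year
or cycle-timepoint cells are empty are dropped with a note (augmented
selection designs are unbalanced by construction). Parents are excluded by
default (configurable). Summaries report each cycle's adjusted mean with a
band of ± 2 genetic standard deviations and significance stars at
p < 0.05/0.01/0.001/0.0001.

# Quality scoring

End-use scores (adjunct and all-malt) award points per trait according to
which band of the trait scale the line's value falls in, then sum over
traits; separate acceptance intervals classify lines against the published
breeding-target regions (ALL_MALT / ADJUNCT / BOTH / NEITHER). The actual
malt-house band tables and numeric targets are not reproduced here: scoring
is entirely configuration-driven, and the shipped
`inst/extdata/score_config.yaml` is an explicitly synthetic, illustrative
configuration used by tests and examples. Bands within a trait must be
disjoint; values outside every band score zero (implicit catch-all); a
missing trait is skipped with a completeness flag, never scored as zero-band.

# The synthetic study generator

`sim_config()` defaults encode the study conditions every stage assumes:
eight parents, seven families crossed to a common parent, cycles C0 = 105,
C1G = 87, C1P = 108, C2G = 114 lines; three trial years with germination at
up to seven after-ripening timepoints on duplicate 30-kernel plates; malting
at TP4/TP6 with a ~55% subset malted at both timepoints, duplicate (SP, ST,
ME, MP) or triplicate (FAN, BG, AA, DP) technical replicates, and a check
inserted every 15 samples; the first year is malted late without
after-ripening control and enters analyses as TP6; the last year grows half
the population. A triallelic dormancy locus drives a saturating
after-ripening curve GI(t) = A t / (t + tau) (A and tau per allele; the
saturating form is this package's choice — the study system is only known
to plateau before ~110 days) with additive pleiotropic effects on the
malting traits; a single-factor polygenic background ties each trait to the
germination-rate factor with loading lambda, so the *within-allele* genetic
correlation with GI equals lambda by construction. Kernel counts are drawn
per plate (binomial germination, multinomial day-of-germination) so the
plate GI statistic is centred on the latent curve. Index selection heavily
weighted toward PHS resistance (low GI at TP1) produces C1P from a noisy
phenotype and C1G/C2G from true breeding values, mirroring phenotypic versus
idealised genomic selection.

Two structural facts matter when interpreting recovery tests. First, under
mid-parent inheritance with Mendelian segregation at half the polygenic
variance, the seven half-sib families yield a base-population variance of
3/4 of the founder polygenic variance (1/4 between family mid-parents +
1/2 segregation), with 7-family sampling noise on top; cross-trait
*correlations* are preserved exactly. Second, family structure makes line
effects non-iid: calibration studies of the genetic-correlation LRT
therefore use a single-biparental-family configuration, where line effects
are iid draws and the test holds its nominal size — under the 7-family
default the same test is anti-conservative, which is a property of the
design, not of the estimator. The generator emulates the statistical
skeleton of a breeding trial, not real grain: there is no linkage map, no
genotype-by-environment interaction beyond additive year effects, no
location structure, and trait scales are realistic but synthetic — so
passing recovery tests demonstrates correctness of the estimators under the
stated model, not agreement with any real data set.

# Problem sizes and scenario choices in the validation suite

The test suite validates each stage at sizes chosen to make the oracle
informative: balanced one-way designs of 50 groups x 4 replicates for the
closed-form equivalence; 500 unstructured lines x 2 years for recovery of a
configured genetic correlation of 0.7 (the after-ripening change channel is
switched off there so the generator's recorded truth and the model's line
effect coincide definitionally); 200 lines x 200 replicates for the null
calibration of the correlation LRT; a single-year population sized to yield
~50 check plots for the plot-error decomposition (truths 64 and 16 in
FAN units squared); 100 lines per cycle for selection-response direction
and variance-halving detection; and the full default design for the
end-to-end determinism check. The full pipeline on the default design runs
in a few minutes on one core.

# Known limitations

* Degrees of freedom are approximate (residual/containment), not exact
  small-sample corrections.
* Only 2-trait unstructured genetic covariance is supported (no n-trait
  structures), matching the bivariate analysis design.
* No spatial or autoregressive residual structures; no kinship or genomic
  relationship matrices — line effects are IID within their structure, as in
  the analysis models this package implements (relationship matrices belong
  to association analysis, which is out of scope; the BLUE tables are the
  documented hand-off point).
* The per-year heritability form and the ratio1 definition
  (sigma2_pltE / sigma2_gTP) are labelled assumptions where only the
  across-year counterparts are standard.
* Genome-wide markers are simulated unlinked and serve only the
  quality-control filters (heterozygosity > 10% and MAF < 0.05 removed,
  boundaries retained, heterozygotes counted as half a dose).
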