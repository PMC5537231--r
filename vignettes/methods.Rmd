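---
title: "Models and methods in swbtwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in swbtwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swbtwin)
```

`swbtwin` links subjective well-being (SWB) to subcortical brain volumes in
twin-family data through five statistical stages, each of which is spelled
out here together with its assumptions, tunable parameters, and the
numerical choices the implementation makes. A companion synthetic-data
generator defines the study conditions under which every stage is tested.

## The kinship linear mixed model

The phenotypic association stage fits, for each region and hemisphere,

$$\mathrm{SWB}_i = \beta_1 Z(v_i) + \beta_2 Z(v_i)^2 +
  \gamma_\mathrm{ICV} Z(\mathrm{ICV}_i) + \gamma_\mathrm{sex} +
  \gamma_\mathrm{age} a_i + \mathrm{study}_i + g_i + e_i,$$

with $\mathrm{cov}(g) = \sigma^2_g K$ and $\mathrm{cov}(e) = \sigma^2_e I$.
$K$ is the expected genetic relatedness: 1 between MZ co-twins, 0.5 between
DZ co-twins and full siblings, 0 across families. $Z(\cdot)$ is the sample
Z-score (mean 0, SD 1, $n-1$ denominator) computed over the pooled sample
across all studies — not per study — because the transform is descriptive,
not inferential. The quadratic term is the square of the Z-scored volume;
refitting with raw volumes is a pure reparameterization of the same fitted
curve, which the test suite asserts (fitted values agree to $10^{-5}$, and
the quadratic-term F statistic is unchanged).

*Estimation.* After one eigendecomposition $K = UDU^\top$ the model is
rotated so the covariance is diagonal, and the variance ratio
$\gamma = \sigma^2_g/\sigma^2_e$ is profiled by a bounded one-dimensional
search on $\log\gamma \in [-14, 14]$ (tolerance $10^{-10}$ on the profile
log-likelihood), with the boundary $\gamma = 0$ checked explicitly. Fixed
effects are the exact GLS solution at the maximizing components. Maximum
likelihood (not REML) is the default, matching the estimation the analysis
chain assumes throughout; REML is available via `reml = TRUE`. Design
columns are rescaled to unit root-mean-square internally so that raw-volume
designs (columns spanning eight orders of magnitude) remain solvable;
estimates are returned on the original scale.

*Testing.* Single coefficients are tested with $F = (\hat\beta/SE)^2$ and
Satterthwaite denominator degrees of freedom
$\mathrm{df} = 2 f(\hat\theta)^2 / (\nabla f^\top \mathcal{I}^{-1} \nabla f)$,
where $f(\theta) = c^\top (X^\top V(\theta)^{-1} X)^{-1} c$ and
$\mathcal{I}$ is the expected information of
$\theta = (\sigma^2_g, \sigma^2_e)$. A residual-df fallback
(`ddf_method = "residual"`) is provided. Multi-coefficient omnibus tests use
the Wald F with the mean of the per-contrast Satterthwaite dfs as
denominator df — a pragmatic single-number summary; the exact multi-df
reference distribution is not attempted. Null simulations at the full
cohort size (724 persons, 500 replicates) show the type-I error of the
single-coefficient test within the 99% binomial interval of the nominal
0.05 and a uniform p-value distribution.

The full scan holds its 14 tests to the Bonferroni level
$0.05/14 = 0.0036$; the study-by-volume interaction omnibus uses
$0.05/4 = 0.0125$ with per-study contrasts against the last study as
reference at 0.05; the twin-model omnibus tests use 0.01. Missing values
are handled by listwise deletion per fitted model, with the dropped count
recorded on the fit object.

## Per-study fits and WLS pooling

The meta-analytic stage refits the region model within each study (without
the study factor) and pools estimates by fixed-effect inverse-variance
weighting: $\hat\beta = \sum w_i \hat\beta_i / \sum w_i$ with
$w_i = 1/SE_i^2$ and pooled SE $(\sum w_i)^{-1/2}$. No heterogeneity
variance is estimated — the pooling is deliberately the plain WLS
combination. The primary p-value is two-tailed normal on
$z = \hat\beta/SE$; a $t_{k-1}$ p-value is reported as a secondary column
because with five studies the two reference distributions differ
appreciably and the appropriate choice is genuinely ambiguous. Pooled
estimates and SEs are asserted in the tests; the pooled p-value's reference
distribution is documented but not asserted. On homogeneous simulated data
the pooled estimate agrees with the all-data (mega-analysis) estimate
within one pooled SE.

## Two-stage least-squares Mendelian randomization

Stage 1 regresses the exposure on its polygenic score plus covariates (sex,
age at MRI, study, and the nuisance principal components) in the kinship
mixed model; the instrument's F gauges strength, with F < 10 flagged weak
but not fatal. Stage 2 regresses the outcome on the *fitted* exposure, the
same covariates, a stratum main effect and a fitted-exposure-by-stratum
interaction. Strata are the tertiles of the stage-1 residuals — contiguous
blocks of the sorted residuals with sizes differing by at most one, lower
strata taking the remainder, ties broken by stable input order — and probe
for nonlinearity of the causal relation. Whether the stratum variable
should enter as main effect plus interaction or interaction only is not
dictated by the design; the default is main effect plus interaction, and
`n_strata = 0` gives the plain second stage (used when comparing against
textbook 2SLS, to which the implementation then agrees to $10^{-8}$).

Naive second-stage SEs treat the fitted exposure as known and understate
uncertainty. The reported SE rescales by the residual variance recomputed
with the observed exposure at the second-stage coefficients (the standard
2SLS correction); both SEs are returned. Coverage simulations (500
replicates, planted causal effect 0.3, nominal 95%) give at least 93%
coverage, and under pure confounding the 2SLS estimate is centered at zero
while naive OLS is biased in the planted direction. `bidirectional_mr()`
runs both causal directions for both hemispheres on the DNA-available
subsample (636 of 724 by default), always including the principal-component
covariates in both stages.

## Multivariate twin covariance modeling

For traits $y$ (SWB, both Z-scored volumes, and their squares; squares are
taken after covariate-free standardization, with study/age/sex carried by
the means model), the expected pair covariances are

$$\Sigma_{MZ} = \begin{pmatrix} \Sigma_A + \Sigma_D + \Sigma_E &
\Sigma_A + \Sigma_D \\ \Sigma_A + \Sigma_D &
\Sigma_A + \Sigma_D + \Sigma_E\end{pmatrix}, \qquad
\Sigma_{DZ}\ \text{with cross-twin blocks}\ \tfrac12\Sigma_A + \tfrac14\Sigma_D,$$

the 0.5 and 0.25 being the expected additive and dominance genetic
correlations among DZ twins. Each included component is parameterized by
its Cholesky factor, so estimates are positive semi-definite by
construction. The per-trait means coefficients are profiled out exactly by
GLS at every likelihood evaluation, leaving the optimizer (quasi-Newton,
relative tolerance $10^{-10}$, up to four deterministic jittered restarts)
to search only the covariance parameters. Pairs are grouped by missingness
pattern and per-group sufficient statistics are precomputed, so likelihood
evaluations cost the same for 50 or 5,000 pairs; incomplete pairs (single
twins) contribute through their observed entries (full-information ML), and
extra siblings are excluded from this stage (they remain in the mixed-model
stages).

The saturated baseline estimates unconstrained MZ and DZ covariance
matrices with the same means model, by an exact ML fixed point
(alternating GLS means and residual covariance) on complete pairs. Because
the biometric fits may additionally use incomplete pairs, likelihood-ratio
comparisons verify that both fits used the same observations and refuse
otherwise; to compare against the saturated model, assemble pairs with
`keep_incomplete = FALSE`. Means are equated across co-twins (twins are
exchangeable), so the saturated covariance is close to, but not exactly,
the sample covariance — the test suite checks it against an independent
direct optimization of the same likelihood instead.

Omnibus tests follow the standard chi-square difference construction:
dropping $\Sigma_D$ from the five-trait ADE model costs 15 parameters;
dropping the four SWB-volume covariances from $\Sigma_A$ (or $\Sigma_E$)
costs 4, implemented by zeroing the first column of the corresponding
Cholesky factor below the diagonal (trait 1 must therefore be SWB).
Dropping a whole variance component places parameters on the boundary of
their space, where the naive chi-square reference is conservative; the LRT
result carries a `boundary` flag and the naive p-value is reported as-is.
Parameter recovery at 5,000 simulated pairs returns AE heritabilities
within ±0.03 of planted values 0.44 and 0.76.

## LD-score regression

The univariate model $E[z_j^2] = N h^2 \ell_j / M + 1$ is fitted by
weighted regression of $z^2$ on the LD score $\ell$, with the standard
heteroskedasticity weights $1/(2(\hat E[z^2])^2 \ell)$ from a first
unweighted pass (an unweighted option is provided); the intercept is free
by default, with a constrained-intercept option. The bivariate stage
regresses $z_{1j} z_{2j}$ on $\ell_j$, giving
$\rho_g = \mathrm{slope} \cdot M/\sqrt{N_1 N_2}$ and
$r_g = \rho_g/\sqrt{h^2_1 h^2_2}$. Standard errors come from a delete-one
block jackknife over 200 contiguous SNP blocks (reduced automatically when
SNPs are few), recomputing the full ratio per left-out block, with
$Z = r_g/SE$ and a two-tailed normal p-value. When an estimated
heritability is nonpositive the correlation is undefined and flagged rather
than reported. Simulations recover a planted $r_g = 0.5$ within two
jackknife SEs in at least 90% of replicates, and the jackknife SE shrinks
with the number of SNPs.

## The synthetic cohort generator

`sim_params()` encodes the study conditions: five studies with the exact
family compositions of the design (26 MZ pairs + 3 single MZ + 1 DZ pair +
1 single DZ in study 1, through 37 MZ pairs + 45 DZ pairs + 9 single DZ +
61 siblings in study 5; 724 persons, 302 male / 422 female), per-study age
means, SDs, ranges and SWB-MRI age correlations, additive heritabilities
0.44 (SWB), 0.76/0.79 (left/right hippocampus), 0.8 (other volumes, ICV),
genetic and environmental SWB-volume correlations 0.07 and 0.18,
left-right genetic/environmental correlations 0.95/0.30, and a planted
volume-SWB link of +0.75 (linear) and −0.33 (quadratic) SWB units per SD.
The negative quadratic coefficient makes the relation concave, so the low
volume stratum ($Z \le -0.5$) has depressed mean SWB while medium and high
strata are comparable. The SWB scale is 24.9 ± 4.1.

Latent additive genetic values are built from a family factor and an
individual factor in a $\sqrt{0.5}/\sqrt{0.5}$ mix, with MZ co-twins
sharing the individual factor too — giving genetic correlations of exactly
1.0 within MZ pairs and 0.5 within DZ/sibling dyads (the generating latents
are retained as an attribute so tests can assert this directly). Dominance
deviations (correlation 0.25 between non-MZ relatives) are available for
ADE calibration but default to zero, matching an AE world. The core
genetic-plus-environmental SWB component is rescaled so the total
phenotypic variance, including the planted volume terms and their
covariance with the core, hits the target variance; empirical variances at
10,000 persons land within 5% of target.

The satisfaction (SAT, 5–35) and happiness (HAP, 4–28) scales are combined
by rescaling HAP linearly onto the SAT range and averaging — the composite
metric is not dictated by the design, and this choice (exposed in
`swb_composite()`) is consistent with a composite mean near 24.9 on the SAT
scale. The stored `swb` column always equals `swb_composite(sat, hap)`
exactly. Scores are clamped to their scale ranges and kept continuous;
item-level responses are not simulated.

Symptom-based ascertainment draws a latent symptom score correlated −0.6
with SWB (chosen once to give group gaps on the scale seen in selected
clinical twin samples) and labels the top/bottom quantile masses of each
selected study high/low, reproducing group sizes such as 23 high / 35 low
in a 58-person study; the truncated-normal closed form for the selected
group means is asserted in tests. Polygenic scores load only on the
additive genetic latents, with loadings set from target incremental
$R^2$ values (0.9% for SWB, 1.7% for hippocampal volume) — deliberately
weak-instrument scale, so first-stage Fs land near 5–11 at the
636-person DNA subsample. One triplet-like family (an MZ pair with an
attached co-sibling) is representable; by default it is labelled as a
sibling attachment, which has the identical kinship structure.

*What the generator does not emulate:* genotype-level data (scores are
ready-made columns), item-level questionnaires, head-size coupling between
ICV and regional volumes (ICV is an independent heritable trait, so
passing tests say nothing about ICV-mediated confounding), scanner or
segmentation artifacts, age trends in volumes, and selection operating on
the volumes themselves. Passing the suite therefore demonstrates that the
estimators recover what they claim under the stated statistical structure,
not that real MRI pipelines are free of these additional complications.

## Problem sizes and runtimes

The test suite standardizes on: 5,000 twin pairs for heritability
recovery, 500 replicates for null calibration (at the 724-person cohort
size) and 2SLS coverage (at 500 unrelated persons), 100 replicates of
bivariate LDSC at 5,000 SNPs, and the default 724-person cohort for
scan-level checks. These sizes make every Monte-Carlo tolerance a
3-standard-error bound or better while keeping the whole suite inside a
few minutes on one CPU. The acceptance script reuses the same sizes.

## Known limitations

- The Satterthwaite approximation uses the expected (not observed)
  information and ML (not REML) components; dfs are approximate, though
  null simulations show calibrated type-I error at the study scale.
- Boundary LRTs (dropping $\Sigma_D$) report the naive chi-square p-value
  with a flag; the proper mixture reference would be less conservative.
- The 2SLS corrected SE is a variance rescaling, not a full sandwich over
  the kinship structure; coverage simulations nevertheless meet the
  nominal level at the sizes tested.
- `pool_fixed()` is fixed-effect only; between-study heterogeneity beyond
  inverse-variance weighting is out of scope.
- LDSC here is the minimal two-parameter regression: no annotation
  stratification, no LD-score computation from genotypes, no
  sample-overlap correction beyond the free intercepts.
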