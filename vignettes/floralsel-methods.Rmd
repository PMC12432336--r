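---
title: "Methods: floral integration and phenotypic selection with floralsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: floral integration and phenotypic selection with floralsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralsel)
```

## Scope and data model

`floralsel` implements the statistical pipeline of a single-population
floral-morphometrics study: a set of plants is tagged in the field, one to
three flowers per plant are measured for ten external floral traits (mm),
female fitness is estimated as the proportion of censused flowers that set
fruit, and a hand-pollination experiment with six treatments characterizes
the mating system. Four analysis stages follow: intrapopulation variation
(CVs, PCA, variance partitioning), phenotypic integration and modularity
(correlation matrices, Mantel tests against module hypotheses,
eigenvalue-variance indices), a fruit-set GLM over the pollination
treatments, and a Lande–Arnold phenotypic selection analysis.

The raw measurements behind the motivating study were not deposited; the
package therefore ships (a) a transcription of the published population
summary (trait means/SDs, CVs with CIs, PC loadings, and the 10 × 10
correlation matrix with CIs and significance flags), which supports every
matrix-level analysis via `fixture_report()`, and (b) a synthetic-data
generator whose defaults restate the published conditions, so every stage
that needs raw data is validated by parameter recovery instead of value
matching.

## Coefficient of variation and its confidence interval

For per-individual trait means \(x_1,\dots,x_n\), \(\mathrm{CV} = 100\,
s/\bar x\) with the \(n-1\) sample SD. Although the source describes CVs on
"standardized" data, a CV of a zero-mean variable is undefined; the only
reading consistent with the published nonzero CVs is the raw-scale CV of
the per-individual means, which is what the package computes (the printed
mean/SD ratios approximate the printed CVs, confirming this reading).

Two CI methods are used, switching at CV = 33%:

* **McKay's approximation** (CV ≤ 33%): limits
  \(100K\,[(u/(\nu+1) - 1)K^2 + u/\nu]^{-1/2}\) with \(K = \mathrm{CV}/100\),
  \(\nu = n - 1\), and \(u\) the \(\chi^2_\nu\) quantiles at \(1-\alpha/2\)
  (lower limit) and \(\alpha/2\) (upper limit). At very small \(n\) the
  upper-limit argument can go non-positive; the limit is then reported as
  unbounded (`Inf`) rather than `NaN`.
* **Noncentral-t inversion** (CV > 33%): the pivot
  \(T = \sqrt{n}\,\bar x / s \sim t_{\nu}(\delta)\) with
  \(\delta = \sqrt{n}/\kappa\) is inverted by root-finding in the
  noncentrality parameter at both tail probabilities, giving
  \(\kappa = \sqrt n/\delta\) limits.

Rebuilding 81-point samples at each published CV reproduces 18 of the 20
published CI bounds exactly at the printed 1-decimal precision, and the
other two within 0.2 (attributable to the 2-decimal rounding of the
printed CVs); this is frozen as a test. Calibration is also checked by
simulation: empirical coverage at \(n = 81\) over 2000 normal samples is
required to fall in 95% ± 2%. A trait is called *uniform* when both the CV
and its CI upper bound are ≤ 10%.

## PCA and variance partitioning

PCA is an eigen-decomposition of the correlation matrix of the input rows
(flower-level rows of the multi-flower subset, matching the source's
design; per-individual means can be passed instead). Loadings are variable
coordinates \(v_{jk}\sqrt{\lambda_k}\); eigenvector sign is arbitrary, so
each axis is oriented to make its largest-magnitude loading positive. The
contribution of trait *j* to axis *k* is
\(100\,\ell_{jk}^2/\sum_j \ell_{jk}^2\) — normalizing by the realized sum
of squares rather than \(\lambda_k\) makes the same formula exact when
applied to loadings transcribed from a printed table.

Variance partitioning uses the one-way random-effects ANOVA
method-of-moments estimators for unbalanced designs: with mean squares
\(MS_a, MS_w\) and effective group size
\(n_0 = (N - \sum n_i^2/N)/(k-1)\),
\(\hat\sigma^2_a = (MS_a - MS_w)/n_0\) (truncated at 0) and
\(\hat\sigma^2_w = MS_w\). The source marks significant variance
components without naming a test; the package uses the one-way ANOVA F
test of the individual factor, the simplest test that is exact under the
normal model. Individuals need at least two flowers (a structural
precondition); individuals left with fewer than two usable values for a
*particular* trait by missingness are dropped for that trait only.

## Integration and modularity

The empirical matrix is pairwise-complete Pearson correlation over
per-individual means, with two-sided p from
\(t = r\sqrt{n-2}/\sqrt{1-r^2}\) and percentile bootstrap CIs (9999
iterations by default) over individuals. Cell significance is taken from
the t-based p rather than the bootstrap CI because the published table's
bold flags contradict its own printed CIs in one cell; three further
marginal cells (printed |r| of 0.19–0.20 against a critical value of
0.2185 at n = 81) differ from the t-test call and are pinned down
explicitly in the tests. Strength classes on |r| resolve the boundary
ambiguity in the source as: weak < 0.3 ≤ moderate < 0.5 ≤ strong.

Three built-in module hypotheses encode which trait pairs are predicted to
correlate (binary matrix, zero diagonal): *morphological* (each whorl a
module: calyx; corolla; androecium; gynoecium), *functional* (visual
attraction = calyx + corolla; pollen export; pollen reception), and
*developmental* (sepals; corolla tube + epipetalous stamens; pistil).
The Mantel statistic is the Pearson correlation of the 45 vectorized
lower-triangle pairs; the null jointly permutes rows and columns of the
hypothesis matrix, and the p-value is one-tailed (greater), since a module
hypothesis predicts positive association — the published p-values are
consistent with that choice. Bootstrap CIs for the Mantel statistic
resample individuals (1000 iterations, 2.5/97.5 percentiles); degenerate
resamples are redrawn and counted. Note the published Mantel CIs do not
contain their own point estimates (a likely transcription issue); the
package's CIs are required by test to behave coherently.

Overall integration is the eigenvalue variance of the correlation matrix,
reported in three variants: raw \(\sum(\lambda_i - 1)^2/N\) (equal to
\(2\sum_{i<j} r_{ij}^2/N\), an identity used as an exact test oracle),
relative (raw/(N−1), in [0, 1], the headline default), and bias-corrected
(raw − (N−1)/n, floored at 0). The published scalar index value (0.11)
cannot be recovered from the printed matrix under any of these variants,
so it is reported but never asserted; the three variants of the printed
matrix are 0.358 / 0.040 / 0.247.

## Mating-system GLM

Fruit set across the six treatments is modelled as a grouped binomial GLM
with complementary log-log link and treatment as the sole factor.
Dispersion is estimated as Pearson \(\chi^2/df\) (the motivating data were
*under*dispersed); both binomial and dispersion-scaled SEs are carried.
The global test reports the raw-deviance LRT \(\chi^2\) *and* a quasi-F
\((\Delta dev/\Delta df)/\hat\phi\), resolving the source's ambiguity
between "quasibinomial" and "LRT" by emitting both. Treatments with 0% or
100% success have infinite link-scale MLEs; the boundary estimate is
reported with a flag and its contrasts are marked non-estimable — no
penalized fitting is applied by default.

"Tukey" post hoc tests on a GLM are interpreted as single-step max-|t|
adjusted contrasts over the estimated contrast correlation matrix (the
general-linear-hypothesis construction; classical HSD assumes Gaussian
ANOVA). The adjustment is evaluated by seeded Monte Carlo on a
multivariate t (20 000 draws by default), with Holm as a cheap fallback,
and summarized as a compact letter display via insert-and-absorb.

**Power caveat.** At the published treatment rates (0, 2.2, 5.6, 33.3,
42.9, 19.1%) and field sample sizes (90/90/90/90/191/178 flowers), two of
the published contrast outcomes are not reproducible with high frequency
under binomial resampling: supplementation vs cross is significant in only
~25% of replicates, and cross vs natural is *non*-significant in only
~50%. The tests therefore assert the contrasts the stated design can
actually separate (e.g. supplementation vs natural/geitonogamy), and this
limitation is documented here rather than tuned away. Similarly, a
treatment with 2.2% success over 90 flowers yields zero fruits — hence a
non-estimable boundary — in about 13% of replicates; that is faithful
behavior, not a failure.

## Selection analysis

Traits are standardized (mean 0, sample SD 1) and fitness relativized,
\(w = W/\bar W\). The opportunity for selection is \(I = Var(w)\), with a
bootstrap SE over individuals (the source's ±-value method is unstated;
bootstrap is the natural seeded choice). Differentials come from simple
regressions per trait (\(S_i\); and \(C_i\) from \(w \sim z + z^2\));
gradients from multiple regressions on the screened trait subset
(\(B_i\); \(Y_{ii}, Y_{ij}\) from the full quadratic model). Quadratic
coefficients are reported both raw (as regression output, apparently what
the published tables print) and doubled (the quadratic-surface convention,
\(\partial^2\hat w/\partial z^2\)); the doubled value is the marked
headline. Inference is OLS on relative fitness, as in the source, even
though fitness is generated binomially — the estimators stay unbiased for
the surface parameters, which is what the recovery tests verify.

Screening before the gradient model follows two rules: keep traits with a
significant among-individual variance share of at least 50% (the source's
worded rule, "varied predominantly between individuals", is descriptive;
50% is the natural majority cutoff and is configurable), then drop one
member of any kept pair with |r| ≥ 0.40, preferring to keep the trait with
the larger |differential|. On published-scale inputs this reproduces the
source's choice (tube width, sepal width, ovary width retained; ovary
length dropped for its r = 0.40 with ovary width). VIFs,
\(1/(1 - R_j^2)\), are computed from the linear design; values above 10
warn rather than fail.

## Synthetic-data generator

The generator states the study's world once and does not move:

* ten traits with the published means and SDs; among-individual
  correlation from a block `module_spec` (default: the four floral whorls
  at within-module r = 0.4, between 0), eigenvalue-clipped to positive
  semidefinite if needed;
* per-trait within-individual variance fraction 0.3 (the published
  tube-width split was ~66/34 among/within), flowers per individual
  uniform on 1–3 (only the range is published);
* fitness through a binomial draw: standardized trait means enter a
  quadratic selection surface \(w(z) = 1 + \beta'z + z'\gamma z/2\)
  (truncated at \(10^{-6}\)), mapped to success probability
  \(p_0 w(z)\) clamped to [0, 1], with \(p_0 = 0.15\) (the published mean
  fruit set) over 30 censused flowers per plant (unpublished; 30 gives
  realistic binomial noise at that mean);
* pollination treatments at the published rates and flower totals.

Non-positive simulated measurements (possible for the two high-CV traits)
are flagged missing, mirroring how impossible field measurements would be
treated. All draws are seeded; the same seed gives bit-identical tables,
and no global RNG state leaks (`with_seed` restores the caller's state).

What a green test establishes: the estimators recover the parameters of
*this* world (multivariate-normal latents, binomial fitness, independent
flower noise). Real floral data may have skewed traits, spatial structure,
or fitness overdispersion that this generator deliberately omits.

## Numerical and design choices

* Missing trait values are explicit `NA`s, excluded pairwise in
  correlations and by complete cases in the selection design, keeping the
  per-statistic N visible.
* Trait order is fixed globally (calyx → corolla → androecium →
  gynoecium); all matrices serialize in that order, and the
  lower-triangle CSV dialect round-trips printed matrices exactly.
* Bootstrap CIs are percentile (2.5/97.5) throughout; no BCa.
* Permutation p-values use the add-one convention, so the resolution is
  \(1/(n_{perm}+1)\) and p is never 0.
* The resampling floor in `run_all()` is 99 iterations; defaults are 999
  permutations and 1000 (Mantel CI) / 9999 (correlation CI) bootstraps.
* Eigenvalue clipping for non-PSD block targets clips at 0 and
  re-normalizes to unit diagonal; the `clipped` attribute records it.

## Known limitations

No mixed-effects fitness models, no partial Mantel or network modularity,
no aster/spline fitness surfaces, and no figure reproduction. The
published scalar integration index and the raw-data-dependent values (LRT
\(\chi^2\), opportunity for selection, coefficient tables) are validated
as procedures by parameter recovery, not by value matching, because the
raw data are unavailable.
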