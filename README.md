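# floralsel

Floral integration and phenotypic selection analysis for
single-population plant studies.

`floralsel` is aimed at pollination biologists and evolutionary
ecologists who measure a handful of floral traits on tagged plants
(a few flowers each), score female fitness as fruit set, and run
hand-pollination experiments. It packages the full analysis chain such a
study needs:

* **Variation** — coefficients of variation with 95% CIs (McKay's
  approximation, switching to a noncentral-*t* inversion above CV = 33%),
  standardized PCA with per-axis variable contributions, and
  among/within-individual variance partitioning (one-way random-effects,
  method of moments).
* **Integration & modularity** — Pearson trait-correlation matrices with
  bootstrap CIs; Mantel tests (999 permutations) of the empirical matrix
  against binary module-hypothesis matrices (morphological, functional,
  developmental criteria built in); eigenvalue-variance integration
  indices.
* **Mating system** — grouped binomial GLM with complementary log-log
  link over six pollination treatments, dispersion estimation, LRT and
  quasi-F global tests, single-step max-|t| adjusted pairwise contrasts
  with a compact letter display.
* **Selection** — Lande–Arnold analysis on standardized traits and
  relativized fitness `w = W / mean(W)`: opportunity for selection
  `I = Var(w)`, selection differentials `S_i`/`C_i` (simple regressions),
  collinearity screening, and gradients `B_i`/`Y_ii`/`Y_ij` (multiple
  regressions) with VIFs.
* **Synthetic data** — a seeded generator with block-modular trait
  correlations, among/within-individual variance, a configurable
  selection surface `w(z) = 1 + β'z + z'γz/2` driving binomial fruit-set
  fitness, and six-treatment pollination experiments, so every estimator
  is validated by parameter recovery.

Because the motivating study's raw measurements were not deposited, the
package ships the published population summary (means, SDs, CVs and CIs,
PC loadings, and the full 10 × 10 correlation matrix) as a plain-text
fixture; `fixture_report()` reruns every matrix-level analysis on it.

## Worked example

```r
library(floralsel)

## 1. Reproduce the published matrix-level results from the fixture
rep <- fixture_report(n_perm = 999, seed = 1)
for (m in rep$mantel)
  cat(sprintf("%-13s r = %.2f  p = %.3f\n", m$criterion, m$r, m$p))
#> morphological r = 0.29  p = 0.027
#> functional    r = 0.21  p = 0.080
#> developmental r = 0.27  p = 0.046
rep$sig_counts[["style_length"]]          # 5 of 9 correlations significant
round(rep$contributions["style_length", "PC1"], 1)  # 27.1 (% of axis 1)

## 2. Simulate a study with directional selection on ovary width
cfg <- sim_config(n_individuals = 90,
                  surface = selection_surface(beta = c(ovary_width = 0.25)))
dat <- simulate_dataset(cfg, seed = 42)
d   <- make_design(filter_for_selection(dat$means, dat$fitness))
opportunity_of_selection(d, n_boot = 1000, seed = 42)
#> n = 89, I = 0.24 (SE 0.04)
s <- selection_differentials(d)
s[s$trait == "ovary_width", c("trait", "S", "S_se", "S_p")]
#>         trait     S   S_se      S_p
#> 9 ovary_width 0.233 0.0458 1.97e-06
```

The Mantel `r` is the Pearson correlation between the 45 off-diagonal
trait-pair correlations and the 0/1 same-module indicators: the
morphological (whorl-based) and developmental partitions fit the
empirical structure (p < 0.05, one-tailed permutation test), the
functional one does not. In the simulation, the configured selection
gradient of 0.25 SD on ovary width is recovered as a significant
differential (0.23 ± 0.05) — the recovery properties are tested
systematically in `tests/testthat/test-acceptance.R`.

A full pipeline run (`run_all()`) takes a YAML/list config with either
CSV inputs or a `simulate` block and writes per-stage CSV/JSON plus a
markdown report; a thin CLI lives at `inst/cli/floralsel.R`
(`simulate`, `run-all`, `fixture-report`).

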