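Package: floralsel
Title: Floral Integration and Phenotypic Selection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing floral trait variation, phenotypic
    integration and modularity, mating-system experiments, and
    Lande-Arnold phenotypic selection in natural plant populations.
    Implements coefficient-of-variation confidence intervals (McKay and
    noncentral-t), standardized PCA with variable contributions,
    among/within-individual variance partitioning, Mantel tests of
    trait-correlation matrices against module hypothesis matrices,
    eigenvalue-variance integration indices, quasibinomial
    complementary log-log fruit-set models with multiplicity-adjusted
    contrasts, and selection differentials and gradients on relative
    fitness, plus a synthetic-data generator with a configurable
    selection surface so every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
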