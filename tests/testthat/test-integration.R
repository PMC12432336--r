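test_that("pearson_matrix: exact correlations, t-test p, strength classes", {
  # exact sample correlation 0.22 at n = 81 -> p just under 0.05
  P <- exact_cor_pair(81, 0.22)
  m <- pearson_matrix(as_means_table(P), traits = c("x", "y"), n_boot = 0)
  expect_equal(m$r["x", "y"], 0.22, tolerance = 1e-12)
  expect_lt(m$p["x", "y"], 0.05)
  expect_gt(m$p["x", "y"], 0.04)  # marginal by design
  expect_equal(unname(m$strength["x", "y"]), "weak")

  # duplicated trait column: r = 1, strong
  D <- cbind(a = P[, 1], b = P[, 1])
  m2 <- pearson_matrix(as_means_table(D), traits = c("a", "b"), n_boot = 0)
  expect_equal(m2$r["a", "b"], 1)
  expect_equal(unname(m2$strength["a", "b"]), "strong")

  # strength boundaries: moderate includes 0.3, strong includes 0.5, on |r|
  S <- exact_cor_pair(50, -0.3, seed = 3)
  m3 <- pearson_matrix(as_means_table(S), traits = c("x", "y"), n_boot = 0)
  expect_equal(unname(m3$strength["x", "y"]), "moderate")

  Z <- cbind(c = rep(5, 20), d = rnorm(20))
  expect_error(pearson_matrix(as_means_table(Z), traits = c("c", "d"), n_boot = 0),
               class = "degenerate_trait_error")
})

test_that("pearson_matrix bootstrap CI is seeded and covers the estimate", {
  cfg <- sim_config(n_individuals = 120, flowers_min = 1, flowers_max = 1,
                    within_fraction = 0)
  m <- suppressWarnings(aggregate_individual_means(simulate_traits(cfg, seed = 2)))
  a <- pearson_matrix(m, n_boot = 300, seed = 5)
  b <- pearson_matrix(m, n_boot = 300, seed = 5)
  expect_identical(a$ci_low, b$ci_low)
  expect_error(pearson_matrix(m, n_boot = 100), class = "parameter_error")
  off <- lower.tri(a$r)
  expect_true(all(a$ci_low[off] <= a$r[off] + 1e-9))
  expect_true(all(a$ci_high[off] >= a$r[off] - 1e-9))
})

test_that("hypothesis matrices match the three module criteria", {
  counts <- c(morphological = 8, functional = 14, developmental = 14)
  for (cr in names(counts)) {
    h <- hypothesis_matrix(cr)
    B <- h$pair_matrix
    expect_equal(sum(B[lower.tri(B)]), unname(counts[cr]))
    expect_identical(B, t(B))
    expect_equal(unname(diag(B)), rep(0, 10))
    # ones-count equals sum of within-module pair counts
    expect_equal(sum(B) / 2, sum(vapply(h$modules, function(m) choose(length(m), 2),
                                        numeric(1))))
  }
  expect_error(hypothesis_matrix("custom", modules = list(a = "sepal_length")),
               class = "parameter_error")
})

test_that("mantel_test: identities, hand oracle, vegan oracle, invariance", {
  fx <- table1_fixture()
  self <- mantel_test(fx$corr, fx$corr, n_perm = 0)
  expect_equal(self$r, 1)

  # 3x3 toy: off-diagonals (0.5, 0.1, 0.1) vs (1, 0, 0) are exactly linear
  A <- diag(3); A[2, 1] <- A[1, 2] <- 0.5
  A[3, 1] <- A[1, 3] <- 0.1; A[3, 2] <- A[2, 3] <- 0.1
  B <- matrix(0, 3, 3); B[2, 1] <- B[1, 2] <- 1
  expect_equal(mantel_test(A, B, n_perm = 0)$r, 1)

  # independent oracle: vegan computes the same statistic
  skip_if_not_installed("vegan")
  set.seed(2)
  M <- cor(matrix(rnorm(300), 30))
  h <- hypothesis_matrix("developmental")
  mine <- mantel_test(M, h, n_perm = 0)$r
  ref <- vegan::mantel(stats::as.dist(M), stats::as.dist(h$pair_matrix),
                       permutations = 0)$statistic
  expect_equal(mine, ref, tolerance = 1e-12)

  # invariance under simultaneous relabeling of both matrices
  pm <- sample(10)
  expect_equal(mantel_test(M[pm, pm], h$pair_matrix[pm, pm], n_perm = 0)$r,
               mine, tolerance = 1e-12)

  # p-value resolution and determinism
  mt <- mantel_test(fx$corr, hypothesis_matrix("morphological"),
                    n_perm = 999, seed = 4)
  expect_identical(mt$p, mantel_test(fx$corr, hypothesis_matrix("morphological"),
                                     n_perm = 999, seed = 4)$p)
  expect_gte(mt$p, 1 / 1000)

  one <- matrix(1, 10, 10)
  expect_error(mantel_test(fx$corr, one - diag(diag(one))),
               class = "undefined_statistic_error")
})

test_that("published matrix yields the published Mantel statistics", {
  fx <- table1_fixture()
  expect_equal(round(mantel_test(fx$corr, hypothesis_matrix("morphological"),
                                 n_perm = 0)$r, 2), 0.29)
  expect_equal(round(mantel_test(fx$corr, hypothesis_matrix("developmental"),
                                 n_perm = 0)$r, 2), 0.27)
  expect_equal(round(mantel_test(fx$corr, hypothesis_matrix("functional"),
                                 n_perm = 0)$r, 2), 0.21)
})

test_that("mantel_bootstrap_ci: power under structure, coverage under null", {
  h <- hypothesis_matrix("morphological")
  # generator matched to the hypothesis: CI excludes 0
  excl <- vapply(1:10, function(i) {
    cfg <- sim_config(n_individuals = 200, flowers_min = 1, flowers_max = 1,
                      within_fraction = 0)
    m <- suppressWarnings(aggregate_individual_means(simulate_traits(cfg, seed = 600 + i)))
    ci <- mantel_bootstrap_ci(m, h, n_boot = 200, seed = i)
    ci$ci_low > 0
  }, logical(1))
  expect_gte(mean(excl), 0.9)

  # null generator (equicorrelated, no modules): CI covers 0 most of the time
  null_mod <- module_spec(list(all = floral_traits()), within_module_r = 0.2)
  cover <- vapply(1:20, function(i) {
    cfg <- sim_config(n_individuals = 100, flowers_min = 1, flowers_max = 1,
                      within_fraction = 0, modules = null_mod)
    m <- suppressWarnings(aggregate_individual_means(simulate_traits(cfg, seed = 700 + i)))
    ci <- mantel_bootstrap_ci(m, h, n_boot = 200, seed = i)
    ci$ci_low <= 0 && ci$ci_high >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.75)
})

test_that("eigenvalue_variance variants and identities", {
  I10 <- diag(10); dimnames(I10) <- list(floral_traits(), floral_traits())
  idx <- eigenvalue_variance(I10, n_individuals = 81)
  expect_equal(unname(idx$all), c(0, 0, 0))

  # equicorrelated rho = 0.3, N = 5: relative index = rho^2
  E <- matrix(0.3, 5, 5); diag(E) <- 1
  expect_equal(eigenvalue_variance(E)$all[["relative"]], 0.09, tolerance = 1e-12)

  # all-ones matrix: maximal integration, relative = 1
  expect_equal(eigenvalue_variance(matrix(1, 6, 6))$all[["relative"]], 1,
               tolerance = 1e-12)

  # algebraic oracle: raw = 2 * sum_{i<j} r_ij^2 / N, exact
  set.seed(8)
  for (i in 1:5) {
    M <- cor(matrix(rnorm(40 * 7), 40))
    ev <- eigenvalue_variance(M)$all
    expect_equal(ev[["raw"]], 2 * sum(M[lower.tri(M)]^2) / 7, tolerance = 1e-10)
    expect_gte(ev[["relative"]], 0); expect_lte(ev[["relative"]], 1)
  }
  expect_error(eigenvalue_variance(matrix(rnorm(9), 3)), class = "parameter_error")
  expect_error(eigenvalue_variance(diag(3), variant = "bias_corrected"),
               class = "parameter_error")
})
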