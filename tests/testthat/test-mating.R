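test_that("cloglog fit: closed-form intercept, saturated proportions, boundary", {
  one <- as_pollination_table(data.frame(
    treatment = "cross", individual_id = paste0("i", 1:3),
    n_flowers = c(30, 30, 30), n_fruits = c(10, 10, 10)))
  fit <- fit_cloglog_binomial(one, ~ 1)
  expect_equal(unname(coef(fit$glm)[1]), log(-log(1 - 1/3)), tolerance = 1e-8)

  gp <- grouped_pollination()
  full <- fit_cloglog_binomial(gp)
  finite <- !full$boundary
  expect_equal(full$fitted[finite], full$observed[finite], tolerance = 1e-8)
  expect_true(full$boundary[["spontaneous_self"]])
  expect_false(any(full$boundary[names(full$boundary) != "spontaneous_self"]))
  expect_true(all(full$fitted >= 0 & full$fitted <= 1))
})

test_that("grouped and disaggregated data give identical coefficients and LRT", {
  gp <- grouped_pollination(p = c(manual_self = 0.1, cross = 0.4, natural = 0.2),
                            n = c(50, 50, 50))
  rows <- do.call(rbind, lapply(seq_len(nrow(gp)), function(i) {
    y <- c(rep(1, gp$n_fruits[i]), rep(0, gp$n_flowers[i] - gp$n_fruits[i]))
    data.frame(treatment = gp$treatment[i],
               individual_id = paste0(gp$individual_id[i], "_", seq_along(y)),
               n_flowers = 1, n_fruits = y)
  }))
  fg <- fit_cloglog_binomial(gp); f1 <- fit_cloglog_binomial(rows)
  expect_equal(coef(fg$glm), coef(f1$glm), tolerance = 1e-8)
  ng <- fit_cloglog_binomial(gp, ~ 1); n1 <- fit_cloglog_binomial(rows, ~ 1)
  lrt_g <- treatment_effect_test(ng, fg)
  lrt_1 <- treatment_effect_test(n1, f1)
  expect_equal(lrt_g$statistic, lrt_1$statistic, tolerance = 1e-8)
  expect_equal(lrt_g$df, 2)
})

test_that("treatment test: identity null, type-I error, power at field design", {
  gp <- grouped_pollination()
  full <- fit_cloglog_binomial(gp)
  same <- treatment_effect_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  cfg_names <- pollination_treatments()
  # equal success probabilities: LRT rejects at ~ alpha
  set.seed(23)
  rej <- replicate(400, {
    tab <- data.frame(treatment = cfg_names, individual_id = cfg_names,
                      n_flowers = 90, n_fruits = rbinom(6, 90, 0.2))
    tab <- as_pollination_table(tab)
    t2 <- treatment_effect_test(fit_cloglog_binomial(tab, ~ 1),
                                fit_cloglog_binomial(tab))
    t2$p < 0.05
  })
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.08)

  # configured field probabilities and sample sizes: overwhelming rejection
  cfg <- sim_config()
  ps <- vapply(1:25, function(i) {
    pol <- simulate_pollination(cfg, seed = 800 + i)
    treatment_effect_test(fit_cloglog_binomial(pol, ~ 1),
                          fit_cloglog_binomial(pol))$p
  }, numeric(1))
  expect_true(all(ps < 0.001))
})

test_that("dispersion is near 1 on true binomial data", {
  set.seed(31)
  tab <- data.frame(treatment = rep(pollination_treatments(), each = 40),
                    individual_id = paste0("i", 1:240),
                    n_flowers = 25)
  tab$n_fruits <- rbinom(240, 25, rep(c(0.05, 0.1, 0.2, 0.3, 0.45, 0.25), each = 40))
  fit <- fit_cloglog_binomial(as_pollination_table(tab))
  expect_gt(fit$dispersion, 0.9); expect_lt(fit$dispersion, 1.1)
})

test_that("pairwise comparisons: identical groups, known separation, letters", {
  # two identical treatments: adjusted p ~ 1
  set.seed(5)
  tab <- data.frame(treatment = rep(c("cross", "natural"), each = 30),
                    individual_id = paste0("i", 1:60), n_flowers = 20)
  tab$n_fruits <- rbinom(60, 20, 0.3)
  pw <- pairwise_comparisons(fit_cloglog_binomial(as_pollination_table(tab)),
                             seed = 2)
  expect_gt(pw$table$p_adjusted[1], 0.2)

  # three groups at 0.1 / 0.1 / 0.9: only the equal pair non-significant
  set.seed(6)
  tab3 <- data.frame(treatment = rep(c("manual_self", "geitonogamy", "cross"),
                                     each = 10),
                     individual_id = paste0("i", 1:30), n_flowers = 20)
  tab3$n_fruits <- rbinom(30, 20, rep(c(0.1, 0.1, 0.9), each = 10))
  fit3 <- fit_cloglog_binomial(as_pollination_table(tab3))
  pw3 <- pairwise_comparisons(fit3, seed = 3)
  t3 <- pw3$table
  eqpair <- t3$level1 == "manual_self" & t3$level2 == "geitonogamy"
  expect_gt(t3$p_adjusted[eqpair], 0.05)
  expect_true(all(t3$p_adjusted[!eqpair] < 0.05))
  # letters consistent with the adjusted p matrix
  expect_equal(pw3$letters[["manual_self"]], pw3$letters[["geitonogamy"]])
  expect_false(pw3$letters[["cross"]] %in%
                 pw3$letters[c("manual_self", "geitonogamy")])
  # adjusted p never below raw
  expect_true(all(t3$p_adjusted >= t3$p_raw - 1e-12))
  # holm fallback agrees on significance calls here
  ph <- pairwise_comparisons(fit3, method = "holm")$table
  expect_equal(ph$p_adjusted < 0.05, t3$p_adjusted < 0.05)
})

test_that("boundary treatments are flagged non-estimable in contrasts", {
  gp <- grouped_pollination()
  pw <- pairwise_comparisons(fit_cloglog_binomial(gp), seed = 7)
  t <- pw$table
  zero <- t$level1 == "spontaneous_self" | t$level2 == "spontaneous_self"
  expect_true(all(!t$estimable[zero]))
  expect_true(all(is.na(t$p_adjusted[zero])))
  expect_true(all(t$estimable[!zero]))
  expect_false("spontaneous_self" %in% names(pw$letters))
})

test_that("field-design simulation separates the clear treatment pairs", {
  # attainable components of the published contrast pattern (see notes in the
  # methods vignette on power limits at the field sample sizes)
  cfg <- sim_config()
  res <- t(vapply(1:20, function(i) {
    pol <- simulate_pollination(cfg, seed = 900 + i)
    pw <- pairwise_comparisons(fit_cloglog_binomial(pol), seed = i,
                               nsim = 5000)$table
    g <- function(a, b) pw$p_adjusted[(pw$level1 == a & pw$level2 == b) |
                                        (pw$level1 == b & pw$level2 == a)]
    c(sup_nat = g("supplementation", "natural") < 0.05,
      sup_geo = g("supplementation", "geitonogamy") < 0.05,
      cross_geo = g("cross", "geitonogamy") < 0.05)
  }, logical(3)))
  # geitonogamy occasionally yields zero fruits (boundary, non-estimable,
  # NA by design); rates are over the estimable replicates
  expect_gte(mean(res[, "sup_nat"], na.rm = TRUE), 0.9)
  expect_gte(mean(res[, "sup_geo"], na.rm = TRUE), 0.9)
  expect_gte(mean(res[, "cross_geo"], na.rm = TRUE), 0.9)
})
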