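make_toy_design <- function(n = 100, seed = 1, beta = 0.25, trait = "ovary_width",
                            p0 = 0.15, flowers = 30) {
  cfg <- sim_config(n_individuals = n, flowers_min = 1, flowers_max = 1,
                    within_fraction = 0, flowers_counted = flowers,
                    surface = selection_surface(beta = setNames(beta, trait),
                                                p0 = p0))
  dat <- simulate_dataset(cfg, seed = seed)
  make_design(filter_for_selection(dat$means, dat$fitness))
}

test_that("make_design standardizes traits and relativizes fitness", {
  d <- make_toy_design(80, seed = 2)
  expect_equal(mean(d$w), 1, tolerance = 1e-10)
  expect_equal(unname(colMeans(d$z)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(d$z, 2, sd)), rep(1, 10), tolerance = 1e-10)

  j <- data.frame(individual_id = 1:3, a = c(1, 2, 3), W = c(0.1, 0.2, 0.3))
  d3 <- make_design(j, traits = "a")
  expect_equal(unname(d3$z[, 1]), c(-1, 0, 1))  # sample SD = 1

  j$b <- 5
  expect_warning(make_design(j, traits = c("a", "b")), "zero-variance")
  j0 <- data.frame(individual_id = 1:3, a = 1:3, W = 0)
  expect_error(make_design(j0, traits = "a"), class = "parameter_error")
})

test_that("opportunity for selection: exact values and seeded bootstrap", {
  d <- list(w = rep(1, 50), W = rep(0.2, 50), n = 50)
  class(d) <- "std_design"
  expect_equal(opportunity_of_selection(d, n_boot = 0)$I, 0)

  W <- rep(c(0, 2), 50)  # w = W / mean(W) = W
  d2 <- structure(list(w = W / mean(W), W = W, n = 100), class = "std_design")
  expect_equal(opportunity_of_selection(d2, n_boot = 0)$I, 100 / 99)

  d3 <- make_toy_design(81, seed = 3)
  a <- opportunity_of_selection(d3, n_boot = 300, seed = 5)
  b <- opportunity_of_selection(d3, n_boot = 300, seed = 5)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("differentials: null slopes vanish, doubling convention holds", {
  d0 <- make_toy_design(2000, seed = 7, beta = 0)
  s0 <- selection_differentials(d0)
  expect_true(all(abs(s0$S) < 0.05))

  d <- make_toy_design(500, seed = 8)
  s <- selection_differentials(d)
  expect_equal(s$C_doubled, 2 * s$C)
  # doubled coefficient equals the curvature of the fitted quadratic surface
  tr <- "ovary_width"
  q <- lm(d$w ~ z + I(z^2), data.frame(w = d$w, z = d$z[, tr]))
  h <- 1e-4
  pred <- function(z) predict(q, data.frame(z = z))
  curv <- (pred(h) - 2 * pred(0) + pred(-h)) / h^2
  expect_equal(unname(curv), s$C_doubled[s$trait == tr], tolerance = 1e-6)
})

test_that("gradients: orthogonality identity, VIF, recovery", {
  # orthogonal standardized predictors: B equals S exactly, VIF = 1
  set.seed(9)
  X <- scale(matrix(rnorm(60 * 3), 60), scale = FALSE)
  z <- qr.Q(qr(X)) * sqrt(59)  # centered, exactly orthogonal, sample SD 1
  w <- 1 + 0.3 * z[, 1] + rnorm(60, 0, 0.1)
  w <- w / mean(w)
  d <- structure(list(z = `colnames<-`(z, c("t1", "t2", "t3")),
                      w = w, W = w, n = 60, traits = c("t1", "t2", "t3")),
                 class = "std_design")
  S <- selection_differentials(d)
  G <- selection_gradients(d, c("t1", "t2", "t3"))
  expect_equal(G$linear$B, S$S, tolerance = 1e-8)
  expect_equal(G$linear$vif, rep(1, 3), tolerance = 1e-10)

  # two predictors correlated at exactly 0.6: VIF = 1/(1 - 0.36)
  P <- exact_cor_pair(100, 0.6, seed = 4)
  expect_equal(unname(vif(P)), rep(1.5625, 2), tolerance = 1e-10)

  # directional recovery on the configured surface (light version of the
  # full acceptance check)
  est <- vapply(1:10, function(i) {
    di <- make_toy_design(500, seed = 1000 + i)
    G <- selection_gradients(di, c("sepal_width", "tube_width", "ovary_width"))
    G$linear$B[G$linear$trait == "ovary_width"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.25), 0.05)
})

test_that("relativization invariance: scaling W changes nothing", {
  d <- make_toy_design(200, seed = 11)
  d_scaled <- d
  d_scaled$W <- d$W * 7.3
  d_scaled$w <- d_scaled$W / mean(d_scaled$W)
  expect_equal(d_scaled$w, d$w, tolerance = 1e-12)
  s1 <- selection_differentials(d)
  s2 <- selection_differentials(d_scaled)
  expect_equal(s1$S, s2$S, tolerance = 1e-12)
  expect_equal(opportunity_of_selection(d, n_boot = 0)$I,
               opportunity_of_selection(d_scaled, n_boot = 0)$I,
               tolerance = 1e-12)
})

test_that("screen_traits applies the variance rule and collinearity rule", {
  tr4 <- c("sepal_width", "tube_width", "ovary_length", "ovary_width")
  vp <- data.frame(trait = c(tr4, "sepal_length"),
                   pct_among = c(64, 66.5, 63.5, 63.2, 30),
                   p_value = c(0.001, 0.001, 0.001, 0.001, 0.4))
  R <- diag(5); dimnames(R) <- list(vp$trait, vp$trait)
  R["ovary_length", "ovary_width"] <- R["ovary_width", "ovary_length"] <- 0.40
  S <- data.frame(trait = vp$trait, S = c(-0.1591, -0.0596, 0.1531, 0.2388, 0.03))
  kept <- screen_traits(vp, R, S = S)
  expect_setequal(as.character(kept), c("sepal_width", "tube_width", "ovary_width"))
  expect_true(any(grepl("ovary_length", attr(kept, "log"))))

  # no pair above the threshold: identity on the variance-rule survivors
  R0 <- diag(5); dimnames(R0) <- dimnames(R)
  expect_setequal(as.character(screen_traits(vp, R0, S = S)), tr4)

  # three mutually correlated traits at 0.9: exactly one survives
  vp3 <- data.frame(trait = c("a", "b", "c"), pct_among = 70, p_value = 0.001)
  R3 <- matrix(0.9, 3, 3); diag(R3) <- 1; dimnames(R3) <- list(vp3$trait, vp3$trait)
  expect_length(as.character(screen_traits(vp3, R3)), 1)

  vp_bad <- data.frame(trait = "a", pct_among = 10, p_value = 0.9)
  expect_error(screen_traits(vp_bad, diag(1)), class = "empty_screen_error")
})
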