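#' Fit the fruit-set GLM across pollination treatments
#'
#' Grouped binomial GLM with complementary log-log link,
#' \eqn{g(p) = \log(-\log(1-p))}, and treatment as the sole factor.
#' Dispersion is estimated as Pearson \eqn{\chi^2 / df}; the returned
#' object carries both binomial and quasi (dispersion-scaled) standard
#' errors. Treatments with 0\% or 100\% observed success have an infinite
#' MLE on the link scale; the boundary estimate is reported as-is with a
#' flag rather than penalized.
#'
#' @param t a pollination table (see [as_pollination_table()]).
#' @param formula model formula on the grouped response; the default fits
#'   treatment as a factor. Use `~ 1` for the null model.
#' @return a `cloglog_fit` list: `glm` (the underlying fit), `dispersion`,
#'   `df_resid`, `deviance`, `pearson_chi2`, `fitted` (per-treatment
#'   probabilities), `observed` (per-treatment proportions), `boundary`
#'   (named logical), `coef`, `se_binomial`, `se_quasi`.
#' @export
fit_cloglog_binomial <- function(t, formula = ~ treatment) {
  t <- as_pollination_table(as.data.frame(t))
  f <- as.formula(paste("cbind(n_fruits, n_flowers - n_fruits)",
                        paste(deparse(formula), collapse = "")))
  fit <- glm(f, family = binomial(link = "cloglog"), data = t)
  pearson <- sum(resid(fit, type = "pearson")^2)
  dfr <- df.residual(fit)
  phi <- if (dfr > 0) pearson / dfr else NA_real_
  obs <- tapply(t$n_fruits, t$treatment, sum) / tapply(t$n_flowers, t$treatment, sum)
  fitted_p <- tapply(fitted(fit) * t$n_flowers, t$treatment, sum) /
    tapply(t$n_flowers, t$treatment, sum)
  sm <- summary(fit)
  structure(list(glm = fit, dispersion = phi, df_resid = dfr,
                 deviance = fit$deviance, pearson_chi2 = pearson,
                 fitted = fitted_p, observed = obs,
                 boundary = setNames(obs == 0 | obs == 1, names(obs)),
                 coef = coef(fit),
                 se_binomial = sm$coefficients[, "Std. Error"],
                 se_quasi = sm$coefficients[, "Std. Error"] * sqrt(max(phi, 0, na.rm = TRUE)),
                 data = t),
            class = "cloglog_fit")
}

#' Global treatment-effect test
#'
#' Compares nested fruit-set models by the deviance difference. Reports the
#' likelihood-ratio chi-square (valid at dispersion 1) and, because grouped
#' fruit-set data are often under- or overdispersed, a quasi-F variant
#' \eqn{F = (\Delta dev / \Delta df) / \hat\phi} with \eqn{\hat\phi} from
#' the full model.
#'
#' @param null_fit,full_fit nested `cloglog_fit` objects on identical data.
#' @return a `treatment_test` list: `statistic` (LRT chi-square), `df`,
#'   `p` (chi-square), `f_statistic`, `p_f`, `dispersion`, `kind`.
#' @export
treatment_effect_test <- function(null_fit, full_fit) {
  d0 <- null_fit$glm; d1 <- full_fit$glm
  same_data <- isTRUE(all.equal(d0$prior.weights, d1$prior.weights)) &&
    nrow(d0$model) == nrow(d1$model)
  if (!same_data || df.residual(d0) < df.residual(d1))
    fs_stop("parameter_error", "models must be nested fits on identical data")
  stat <- max(d0$deviance - d1$deviance, 0)
  df <- df.residual(d0) - df.residual(d1)
  phi <- full_fit$dispersion
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  fstat <- if (df > 0 && is.finite(phi) && phi > 0) (stat / df) / phi else NA_real_
  pf_ <- if (df > 0 && is.finite(fstat))
    pf(fstat, df, df.residual(d1), lower.tail = FALSE) else if (df == 0) 1 else NA_real_
  structure(list(statistic = stat, df = df, p = p,
                 f_statistic = fstat, p_f = pf_, dispersion = phi,
                 kind = "LRT+quasiF"),
            class = "treatment_test")
}

#' Multiplicity-adjusted pairwise treatment contrasts
#'
#' All pairwise contrasts between treatment means on the link scale.
#' `single-step` adjusts by the max-|t| distribution over the estimated
#' contrast correlation matrix (the standard general-linear-hypothesis
#' construction that generalizes Tukey's HSD to GLMs), evaluated by seeded
#' Monte Carlo on a multivariate t; `holm` is the sequential fallback.
#' Standard errors use the quasi (dispersion-scaled) covariance. Contrasts
#' involving a boundary treatment (0\% or 100\% observed success, infinite
#' link-scale MLE) are flagged non-estimable and excluded from adjustment
#' and lettering.
#'
#' @param fit a `cloglog_fit` with a treatment factor.
#' @param method `"single-step"` or `"holm"`.
#' @param seed integer seed for the Monte Carlo adjustment.
#' @param nsim Monte Carlo draws for `single-step` (default 20000).
#' @return a `pairwise_comparisons` list: `table` (data.frame with
#'   `pair`, `estimate` on the link scale, `se`, `t`, `p_raw`,
#'   `p_adjusted`, `estimable`), `letters` (compact letter display over
#'   estimable treatments), `method`.
#' @export
pairwise_comparisons <- function(fit, method = c("single-step", "holm"),
                                 seed = 1L, nsim = 20000) {
  method <- match.arg(method)
  g <- fit$glm
  lev <- levels(g$model$treatment)
  if (is.null(lev)) fs_stop("parameter_error", "fit has no treatment factor")
  # treatment means on the link scale: L %*% coef
  mm <- model.matrix(~ treatment, data = data.frame(treatment = factor(lev, levels = lev)))
  pairs <- utils::combn(length(lev), 2)
  Lc <- mm[pairs[1, ], , drop = FALSE] - mm[pairs[2, ], , drop = FALSE]
  phi <- fit$dispersion
  V <- vcov(g) * if (is.finite(phi) && phi > 0) phi else 1
  est <- drop(Lc %*% coef(g))
  se <- sqrt(pmax(diag(Lc %*% V %*% t(Lc)), 0))
  tval <- est / se
  dfr <- fit$df_resid
  estimable <- !(fit$boundary[lev[pairs[1, ]]] | fit$boundary[lev[pairs[2, ]]])
  tval[!estimable] <- NA_real_  # infinite-MLE contrasts are not testable
  p_raw <- p_adj <- rep(NA_real_, length(tval))
  # zero residual df (fully saturated grouped data) leaves no error estimate
  ok <- if (dfr >= 1) which(estimable) else integer(0)
  p_raw[ok] <- 2 * pt(-abs(tval[ok]), dfr)
  if (length(ok)) {
    if (method == "holm") {
      p_adj[ok] <- p.adjust(p_raw[ok], "holm")
    } else {
      Rk <- Lc[ok, , drop = FALSE] %*% V %*% t(Lc[ok, , drop = FALSE])
      Rk <- stats::cov2cor(Rk)
      maxabs <- with_seed(seed, {
        z <- MASS::mvrnorm(nsim, mu = rep(0, nrow(Rk)), Sigma = Rk)
        s <- sqrt(rchisq(nsim, dfr) / dfr)
        apply(abs(z), 1, max) / s
      })
      p_adj[ok] <- vapply(abs(tval[ok]),
                          function(tt) mean(maxabs >= tt), numeric(1))
      p_adj[ok] <- pmax(p_adj[ok], p_raw[ok])  # adjusted p never below raw
    }
  }
  tab <- data.frame(
    pair = paste(lev[pairs[1, ]], lev[pairs[2, ]], sep = " - "),
    level1 = lev[pairs[1, ]], level2 = lev[pairs[2, ]],
    estimate = est, se = se, t = tval,
    p_raw = p_raw, p_adjusted = p_adj, estimable = estimable)
  letters <- compact_letters(lev[!fit$boundary[lev]], tab)
  structure(list(table = tab, letters = letters, method = method,
                 dispersion = phi),
            class = "pairwise_comparisons")
}

#' Compact letter display from an adjusted p-value table
#'
#' Insert-and-absorb algorithm: starting from one letter covering all
#' groups, each significantly different pair (adjusted p < `alpha`) splits
#' the letters containing both members; redundant letters are absorbed.
#' Groups sharing a letter are not significantly different.
#'
#' @param groups character vector of group names to letter.
#' @param tab contrast table with `level1`, `level2`, `p_adjusted`.
#' @param alpha significance level.
#' @return named character vector of letter strings.
#' @export
compact_letters <- function(groups, tab, alpha = 0.05) {
  sets <- list(groups)
  sig <- tab[!is.na(tab$p_adjusted) & tab$p_adjusted < alpha &
               tab$level1 %in% groups & tab$level2 %in% groups, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$level1[i]; b <- sig$level2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) for (k in seq_along(new_sets))
      if (j != k && keep[j] && keep[k] &&
          all(new_sets[[j]] %in% new_sets[[k]])) keep[j] <- FALSE
    sets <- unique(new_sets[keep])
  }
  out <- setNames(rep("", length(groups)), groups)
  for (j in seq_along(sets))
    for (gname in sets[[j]]) out[gname] <- paste0(out[gname], letters[j])
  out
}
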