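#' Coefficient of variation with 95% confidence interval
#'
#' CV is computed on the raw per-individual trait means as
#' \eqn{100\, s / \bar{x}} (sample SD, denominator \eqn{n-1}). For CVs at or
#' below `noncentral_cutoff` (33\%) the CI uses McKay's chi-square
#' approximation; above it the CI is obtained by inverting the noncentral-t
#' pivot \eqn{T = \sqrt{n}\,\bar{x}/s \sim t_{n-1}(\sqrt{n}/\kappa)}, which
#' remains accurate for large CVs where McKay degrades. A trait is flagged
#' `uniform` when both the point estimate and the CI upper bound are at or
#' below `uniform_threshold` (10\%).
#'
#' @param values numeric vector of per-individual trait means (must be
#'   positive on average); `NA`s dropped.
#' @param alpha two-sided error rate (default 0.05).
#' @param noncentral_cutoff CV (\%) above which the noncentral-t inversion
#'   replaces McKay's approximation.
#' @param uniform_threshold CV (\%) bound for the uniformity rule.
#' @return a one-row `cv_result` data.frame: `cv`, `ci_low`, `ci_high`
#'   (all \%), `n`, `method` (`"mckay"`, `"noncentral_t"` or
#'   `"degenerate"`), `uniform`.
#' @export
#' @examples
#' coefficient_of_variation(c(8, 10, 12))  # cv = 20
coefficient_of_variation <- function(values, alpha = 0.05,
                                     noncentral_cutoff = 33,
                                     uniform_threshold = 10) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3) fs_stop("parameter_error", "need at least 3 observations")
  m <- mean(x)
  if (m <= 0) fs_stop("undefined_cv_error", "CV undefined for non-positive mean")
  s <- sd(x)
  cv <- 100 * s / m
  if (s == 0) {
    res <- data.frame(cv = 0, ci_low = 0, ci_high = 0, n = n,
                      method = "degenerate", uniform = TRUE)
    class(res) <- c("cv_result", "data.frame")
    return(res)
  }
  nu <- n - 1
  if (cv <= noncentral_cutoff) {
    K <- cv / 100
    lim <- function(u) {
      arg <- (u / (nu + 1) - 1) * K^2 + u / nu
      if (arg <= 0) Inf else 100 * K / sqrt(arg)  # unbounded at tiny n
    }
    ci_low <- lim(qchisq(1 - alpha / 2, nu))
    ci_high <- lim(qchisq(alpha / 2, nu))
    method <- "mckay"
  } else {
    t_obs <- sqrt(n) * m / s
    # delta bounds: P(T >= t_obs | delta_L) = alpha/2, = 1 - alpha/2 for delta_U
    solve_ncp <- function(target) {
      # pnt's "full precision" warning at large ncp is expected and harmless
      f <- function(d) suppressWarnings(pt(t_obs, df = nu, ncp = d)) - target
      hi <- t_obs + 10 * (1 + abs(t_obs))
      while (f(hi) > 0) hi <- hi * 2
      uniroot(f, lower = 1e-8, upper = hi, tol = 1e-10)$root
    }
    delta_low <- solve_ncp(1 - alpha / 2)   # small ncp -> wide CV
    delta_high <- solve_ncp(alpha / 2)      # large ncp -> narrow CV
    ci_low <- 100 * sqrt(n) / delta_high
    ci_high <- 100 * sqrt(n) / delta_low
    method <- "noncentral_t"
  }
  res <- data.frame(cv = cv, ci_low = ci_low, ci_high = ci_high, n = n,
                    method = method,
                    uniform = cv <= uniform_threshold && ci_high <= uniform_threshold)
  class(res) <- c("cv_result", "data.frame")
  res
}

#' CV table for every trait
#'
#' @param means an `individual_traits` table.
#' @param traits trait columns to summarize.
#' @inheritParams coefficient_of_variation
#' @return data.frame with one `cv_result` row per trait.
#' @export
cv_table <- function(means, traits = floral_traits(), alpha = 0.05) {
  rows <- lapply(traits, function(tr) {
    r <- coefficient_of_variation(means[[tr]], alpha = alpha)
    cbind(trait = tr, r)
  })
  do.call(rbind, rows)
}

#' Standardized principal component analysis
#'
#' PCA on the correlation matrix of the input rows (each trait centred and
#' scaled), i.e. an eigen-decomposition of `cor(X)`. Loadings are variable
#' coordinates (eigenvector times the square root of its eigenvalue); the
#' sign of each axis is fixed so its largest-magnitude loading is positive.
#' The contribution of trait *j* to axis *k* is
#' \eqn{100\, \ell_{jk}^2 / \sum_j \ell_{jk}^2}, which for exact loadings
#' equals the squared eigenvector entry.
#'
#' @param x a `flower_table` or `individual_traits` table (id columns are
#'   dropped); only complete rows are used.
#' @param traits trait columns to include; constant traits are excluded
#'   with a warning.
#' @return a `pca_result` list: `loadings` (traits x axes), `eigenvalues`,
#'   `explained_pct` (nonincreasing, sums to 100), `contributions_pct`
#'   (each column sums to 100), `n`.
#' @export
pca_standardized <- function(x, traits = floral_traits()) {
  X <- as.matrix(as.data.frame(x)[, traits, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 2) fs_stop("parameter_error", "need at least 2 complete rows")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("excluding constant trait(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  R <- cor(X)
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = ncol(X))
  # sign convention: dominant loading on each axis positive
  for (k in seq_len(ncol(L)))
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(ncol(L))))
  structure(list(loadings = L,
                 eigenvalues = e$values,
                 explained_pct = 100 * e$values / sum(e$values),
                 contributions_pct = pca_contributions(L),
                 n = nrow(X)),
            class = "pca_result")
}

#' Per-axis variable contributions from loadings
#'
#' Contribution of trait *j* to axis *k* as a percentage:
#' \eqn{100\, \ell_{jk}^2 / \sum_j \ell_{jk}^2}. Normalizing by the realized
#' sum of squares (rather than the eigenvalue) makes the same formula exact
#' for loadings transcribed from a printed table at 2-decimal precision.
#'
#' @param loadings numeric matrix (or vector) of loadings, traits in rows.
#' @return matrix of contributions; each column sums to 100.
#' @export
pca_contributions <- function(loadings) {
  L <- as.matrix(loadings)
  sq <- L^2
  sweep(sq, 2, colSums(sq), `/`) * 100
}

#' Among/within-individual variance partition for one trait
#'
#' One-way random-effects decomposition using the ANOVA method-of-moments
#' estimators for unbalanced designs: with mean squares \eqn{MS_a} (among
#' individuals) and \eqn{MS_w} (within) and effective group size
#' \eqn{n_0 = (N - \sum n_i^2 / N) / (k - 1)}, the components are
#' \eqn{\sigma^2_a = (MS_a - MS_w)/n_0} (truncated at 0) and
#' \eqn{\sigma^2_w = MS_w}. Significance of the among-individual component
#' is the one-way ANOVA F test.
#'
#' @param t a `flower_table` in which every individual has at least two
#'   flowers (run [filter_multiflower()] first).
#' @param trait trait column name.
#' @return one-row `variance_partition` data.frame: `trait`, `var_among`,
#'   `var_within`, `pct_among`, `pct_within`, `f_statistic`, `p_value`, `n`.
#' @export
variance_partition <- function(t, trait) {
  if (any(table(t$individual_id) < 2))
    fs_stop("precondition_error",
            "all individuals need >= 2 flowers; run filter_multiflower() first")
  d <- data.frame(y = t[[trait]], g = factor(t$individual_id))
  d <- d[!is.na(d$y), , drop = FALSE]
  ni <- table(d$g)
  # individuals left with < 2 usable values for THIS trait (missing cells)
  # cannot inform the within component; drop them
  short <- names(ni)[ni < 2]
  if (length(short)) {
    d <- d[!(as.character(d$g) %in% short), , drop = FALSE]
    d$g <- droplevels(d$g)
    ni <- table(d$g)
  }
  N <- nrow(d); k <- length(ni)
  fit <- lm(y ~ g, data = d)
  a <- anova(fit)
  ms_a <- a$`Mean Sq`[1]; ms_w <- a$`Mean Sq`[2]
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  var_among <- max((ms_a - ms_w) / n0, 0)
  var_within <- ms_w
  tot <- var_among + var_within
  res <- data.frame(trait = trait, var_among = var_among, var_within = var_within,
                    pct_among = 100 * var_among / tot,
                    pct_within = 100 * var_within / tot,
                    f_statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1], n = N)
  class(res) <- c("variance_partition", "data.frame")
  res
}

#' Variance partition table for every trait
#' @param t a multi-flower `flower_table`.
#' @param traits trait columns.
#' @return stacked [variance_partition()] rows.
#' @export
variance_partition_table <- function(t, traits = floral_traits()) {
  do.call(rbind, lapply(traits, function(tr) variance_partition(t, tr)))
}
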