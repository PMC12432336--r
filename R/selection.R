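#' Standardized design for selection analysis
#'
#' Builds the regression inputs of a Lande-Arnold analysis: trait values
#' standardized to mean 0, SD 1 (sample SD) and fitness relativized by the
#' population mean, \eqn{w = W / \bar W}, so gradients are in units of
#' phenotypic standard deviations and selection intensities.
#'
#' @param joined output of [filter_for_selection()] (trait means plus `W`),
#'   or pass `traits` and `fit` separately.
#' @param traits trait columns to standardize; zero-variance traits are
#'   excluded with a warning.
#' @return a `std_design` list: `z` (individuals x traits), `w`, `W`, `n`,
#'   `traits`, `individual_id`.
#' @export
make_design <- function(joined, traits = floral_traits()) {
  d <- as.data.frame(joined)
  stopifnot("W" %in% names(d))
  keep <- complete.cases(d[, c(traits, "W")])
  d <- d[keep, , drop = FALSE]
  if (all(d$W == 0)) fs_stop("parameter_error", "all fitness values are zero")
  X <- as.matrix(d[, traits, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance trait(s): ",
            paste(traits[sds == 0], collapse = ", "))
    traits <- traits[sds > 0]
    X <- X[, traits, drop = FALSE]
  }
  z <- scale(X)
  w <- d$W / mean(d$W)
  structure(list(z = z, w = w, W = d$W, n = nrow(d), traits = traits,
                 individual_id = d$individual_id),
            class = "std_design")
}

#' Opportunity for selection
#'
#' The variance of relative fitness, \eqn{I = Var(w)} (sample variance,
#' denominator \eqn{n-1}): the upper bound on the change in any trait's
#' standardized mean achievable by selection. The SE is the bootstrap SD
#' over individuals; relative fitness is re-relativized in each resample.
#'
#' @param d a `std_design`.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return an `opportunity_result` list: `I`, `se`, `n_boot`, `n`.
#' @export
opportunity_of_selection <- function(d, n_boot = 1000, seed = NULL) {
  stopifnot(d$n >= 3)
  I <- var(d$w)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) fs_stop("parameter_error", "bootstrap requires a seed")
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      Wb <- d$W[sample.int(d$n, replace = TRUE)]
      if (mean(Wb) == 0) return(NA_real_)
      var(Wb / mean(Wb))
    }, numeric(1)))
    se <- sd(reps, na.rm = TRUE)
  }
  structure(list(I = I, se = se, n_boot = n_boot, n = d$n),
            class = "opportunity_result")
}

# one coefficient row with OLS SE and two-sided p
coef_row <- function(fit, term) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) return(c(NA_real_, NA_real_, NA_real_))
  sm[term, c("Estimate", "Std. Error", "Pr(>|t|)")]
}

#' Selection differentials (total selection)
#'
#' Per trait, two regressions of relative fitness on the standardized
#' trait: the simple linear slope is the linear differential \eqn{S_i}
#' (total directional selection, including indirect selection through
#' correlated traits); the quadratic model \eqn{w \sim z + z^2} gives the
#' nonlinear differential \eqn{C_i} as the raw \eqn{z^2} coefficient,
#' reported alongside its doubled value (the conventional quadratic
#' scale, since \eqn{\partial^2 w/\partial z^2 = 2 C_i}).
#'
#' @param d a `std_design`.
#' @return a `selection_result` data.frame: one row per trait with `S`,
#'   `S_se`, `S_p`, `C`, `C_doubled`, `C_se`, `C_p`.
#' @export
selection_differentials <- function(d) {
  stopifnot(d$n > 3)
  rows <- lapply(d$traits, function(tr) {
    dat <- data.frame(w = d$w, z = d$z[, tr])
    lin <- coef_row(lm(w ~ z, dat), "z")
    qd <- lm(w ~ z + I(z^2), dat)
    quad <- coef_row(qd, "I(z^2)")
    data.frame(trait = tr, S = lin[1], S_se = lin[2], S_p = lin[3],
               C = quad[1], C_doubled = 2 * quad[1],
               C_se = quad[2], C_p = quad[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("selection_result", "data.frame")
  out
}

#' Screen traits for the gradient analysis
#'
#' Applies the two screening rules used before fitting selection gradients:
#' (1) keep traits whose among-individual variance share is significant and
#' at least `among_floor` percent (traits must vary repeatably between
#' plants for selection on plant means to be interpretable); (2) among the
#' kept traits, for every pair correlated at \eqn{|r| \ge} `r_threshold`
#' drop one member to limit collinearity - by default the member with the
#' smaller absolute linear differential (ties and missing differentials
#' fall back to trait order). All decisions are logged.
#'
#' @param varpart output of [variance_partition_table()].
#' @param corr a `corr_matrix` (or plain correlation matrix).
#' @param S optional `selection_result` with differentials for tie-breaks.
#' @param r_threshold collinearity cutoff on \eqn{|r|} (default 0.40).
#' @param among_floor minimum among-individual variance share in percent
#'   (default 50).
#' @param alpha significance level for the variance component.
#' @return character vector of retained traits, with attribute `log`
#'   (character vector of decisions).
#' @export
screen_traits <- function(varpart, corr, S = NULL, r_threshold = 0.40,
                          among_floor = 50, alpha = 0.05) {
  log <- character(0)
  ok <- varpart$p_value < alpha & varpart$pct_among >= among_floor
  kept <- varpart$trait[ok]
  for (tr in varpart$trait[!ok])
    log <- c(log, sprintf(
      "drop %s: among-individual share %.1f%% (p = %.3g) fails the variance rule",
      tr, varpart$pct_among[varpart$trait == tr],
      varpart$p_value[varpart$trait == tr]))
  rmat <- as_corr(corr)
  Sval <- if (!is.null(S)) setNames(abs(S$S), S$trait) else NULL
  repeat {
    if (length(kept) < 2) break
    sub <- abs(rmat[kept, kept, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) < r_threshold) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- kept[idx]
    drop_tr <- if (!is.null(Sval) && !anyNA(Sval[pair]) &&
                   Sval[pair[1]] != Sval[pair[2]])
      pair[which.min(Sval[pair])] else pair[2]
    log <- c(log, sprintf("drop %s: |r| = %.2f with %s (threshold %.2f)",
                          drop_tr, max(sub), setdiff(pair, drop_tr), r_threshold))
    kept <- setdiff(kept, drop_tr)
  }
  if (length(kept) == 0)
    fs_stop("empty_screen_error",
            "no traits survive screening; relax among_floor or r_threshold")
  structure(kept, log = log)
}

#' Variance inflation factors of a linear design
#'
#' \eqn{VIF_j = 1 / (1 - R_j^2)} where \eqn{R_j^2} is from regressing
#' predictor *j* on the remaining predictors.
#'
#' @param z numeric matrix of predictors (>= 2 columns).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(z) {
  z <- as.matrix(z)
  stopifnot(ncol(z) >= 2)
  vapply(seq_len(ncol(z)), function(j) {
    r2 <- summary(lm(z[, j] ~ z[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(z))
}

#' Selection gradients (direct selection)
#'
#' Multiple regressions of relative fitness on the standardized traits of
#' `subset`: the linear model gives directional gradients \eqn{B_i}
#' (direct selection, holding the other traits constant); the full
#' quadratic model (all traits, their squares, and pairwise products)
#' gives quadratic gradients \eqn{Y_{ii}} (raw and doubled) and
#' correlational gradients \eqn{Y_{ij}}. VIFs come from the linear design;
#' values above `vif_ceiling` raise a warning, not an error.
#'
#' @param d a `std_design`.
#' @param subset traits to include (>= 2, e.g. from [screen_traits()]).
#' @param vif_ceiling collinearity warning threshold (default 10).
#' @return a `gradient_result` list: `linear` (data.frame `trait`, `B`,
#'   `B_se`, `B_p`, `vif`), `quadratic` (`trait`, `Y_ii`, `Y_ii_doubled`,
#'   `Y_se`, `Y_p`), `correlational` (`pair`, `Y_ij`, `Y_se`, `Y_p`), `n`.
#' @export
selection_gradients <- function(d, subset, vif_ceiling = 10) {
  subset <- as.character(subset)
  stopifnot(length(subset) >= 2, all(subset %in% d$traits))
  z <- d$z[, subset, drop = FALSE]
  n_par_quad <- 1 + 2 * length(subset) + choose(length(subset), 2)
  if (d$n <= n_par_quad)
    fs_stop("parameter_error", "too few individuals for the quadratic model")
  dat <- data.frame(w = d$w, z, check.names = FALSE)
  lin_f <- as.formula(paste("w ~", paste(sprintf("`%s`", subset), collapse = " + ")))
  lin <- lm(lin_f, dat)
  v <- vif(z)
  if (any(v > vif_ceiling))
    warning("VIF above ", vif_ceiling, " for: ",
            paste(names(v)[v > vif_ceiling], collapse = ", "))
  linear <- do.call(rbind, lapply(subset, function(tr) {
    cr <- coef_row(lin, sprintf("`%s`", tr))
    if (anyNA(cr)) cr <- coef_row(lin, tr)
    data.frame(trait = tr, B = cr[1], B_se = cr[2], B_p = cr[3],
               vif = unname(v[tr]))
  }))
  # raw z^2 and z_i z_j terms: coefficients are regression-scale, doubled
  # values give the quadratic-surface convention
  sq_terms <- sprintf("I(`%s`^2)", subset)
  pr <- utils::combn(subset, 2)
  pr_terms <- sprintf("I(`%s` * `%s`)", pr[1, ], pr[2, ])
  quad_f <- as.formula(paste("w ~",
    paste(c(sprintf("`%s`", subset), sq_terms, pr_terms), collapse = " + ")))
  qfit <- lm(quad_f, dat)
  quadratic <- do.call(rbind, lapply(seq_along(subset), function(i) {
    cr <- coef_row(qfit, sq_terms[i])
    data.frame(trait = subset[i], Y_ii = cr[1], Y_ii_doubled = 2 * cr[1],
               Y_se = cr[2], Y_p = cr[3])
  }))
  correlational <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
    cr <- coef_row(qfit, pr_terms[k])
    data.frame(pair = paste(pr[1, k], pr[2, k], sep = " x "),
               trait1 = pr[1, k], trait2 = pr[2, k],
               Y_ij = cr[1], Y_se = cr[2], Y_p = cr[3])
  }))
  rownames(linear) <- rownames(quadratic) <- rownames(correlational) <- NULL
  structure(list(linear = linear, quadratic = quadratic,
                 correlational = correlational, n = d$n,
                 linear_fit = lin, quadratic_fit = qfit),
            class = "gradient_result")
}
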