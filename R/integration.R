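#' Empirical Pearson correlation matrix with bootstrap CIs
#'
#' Pairwise-complete Pearson correlations among per-individual trait means,
#' with two-sided p-values from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}},
#' percentile bootstrap CIs from resampling individuals, and a qualitative
#' strength class on \eqn{|r|}: weak below 0.3, moderate in \[0.3, 0.5),
#' strong at or above 0.5.
#'
#' @param means an `individual_traits` table.
#' @param traits trait columns.
#' @param n_boot bootstrap iterations (default 9999).
#' @param seed integer seed for the bootstrap (required when `n_boot > 0`).
#' @param conf confidence level (default 0.95).
#' @return a `corr_matrix` list: `r`, `p`, `n` (pairwise sample sizes),
#'   `ci_low`, `ci_high`, `significant` (p below `1 - conf`), `strength`
#'   (character matrix), `traits`.
#' @export
pearson_matrix <- function(means, traits = floral_traits(), n_boot = 9999,
                           seed = NULL, conf = 0.95) {
  X <- as.matrix(as.data.frame(means)[, traits, drop = FALSE])
  sds <- apply(X, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    fs_stop("degenerate_trait_error", paste(
      "zero-variance trait(s):", paste(traits[!is.finite(sds) | sds == 0], collapse = ", ")))
  r <- cor(X, use = "pairwise.complete.obs")
  cc <- !is.na(X)
  npair <- crossprod(cc)
  tval <- r * sqrt(npair - 2) / sqrt(pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tval), df = pmax(npair - 2, 1))
  diag(p) <- NA_real_
  ci_low <- ci_high <- NULL
  if (n_boot > 0) {
    if (is.null(seed)) fs_stop("parameter_error", "bootstrap requires a seed")
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        cor(X[idx, , drop = FALSE], use = "pairwise.complete.obs")
      }, r)
    })
    a <- (1 - conf) / 2
    ci_low <- apply(boots, c(1, 2), quantile, probs = a, na.rm = TRUE)
    ci_high <- apply(boots, c(1, 2), quantile, probs = 1 - a, na.rm = TRUE)
  }
  strength <- matrix(cut(abs(r), c(-Inf, 0.3, 0.5, Inf),
                         labels = c("weak", "moderate", "strong"), right = FALSE),
                     nrow(r), dimnames = dimnames(r))
  structure(list(r = r, p = p, n = npair, ci_low = ci_low, ci_high = ci_high,
                 significant = p < (1 - conf), strength = strength,
                 traits = traits),
            class = "corr_matrix")
}

# accept corr_matrix, floral_fixture, module_hypothesis or plain matrix
as_corr <- function(x) {
  if (inherits(x, "corr_matrix")) return(x$r)
  if (inherits(x, "floral_fixture")) return(x$corr)
  if (inherits(x, "module_hypothesis")) return(x$pair_matrix)
  as.matrix(x)
}

#' Binary module hypothesis matrix
#'
#' Builds the trait-pair indicator matrix for a modularity hypothesis:
#' entry 1 where two traits are predicted to belong to the same module
#' (hence to be correlated), 0 otherwise, zero diagonal. Three built-in
#' criteria are provided. *Morphological*: each floral whorl is a module
#' (calyx; corolla; androecium; gynoecium). *Functional*: modules by role —
#' visual attraction (calyx plus corolla), pollen export (androecium),
#' pollen reception (gynoecium). *Developmental*: modules by ontogenetic
#' origin — sepals; the corolla tube with its epipetalous stamens; pistil.
#'
#' @param criterion `"morphological"`, `"functional"`, `"developmental"`,
#'   or `"custom"` (then supply `modules`).
#' @param trait_order trait order for the matrix.
#' @param modules named list of trait vectors for `criterion = "custom"`.
#' @return a `module_hypothesis` list: `criterion`, `modules`,
#'   `pair_matrix` (0/1, symmetric, zero diagonal).
#' @export
hypothesis_matrix <- function(criterion = c("morphological", "functional",
                                            "developmental", "custom"),
                              trait_order = floral_traits(), modules = NULL) {
  criterion <- match.arg(criterion)
  tr <- floral_traits()
  builtin <- list(
    morphological = list(calyx = tr[1:2], corolla = tr[3:5],
                         androecium = tr[6:7], gynoecium = tr[8:10]),
    functional = list(visual_attraction = tr[1:5], pollen_export = tr[6:7],
                      pollen_reception = tr[8:10]),
    developmental = list(sepals = tr[1:2], epipetalous_stamens = tr[3:7],
                         pistil = tr[8:10]))
  if (criterion == "custom") {
    if (is.null(modules)) fs_stop("parameter_error", "custom criterion needs modules")
  } else modules <- builtin[[criterion]]
  flat <- unlist(modules, use.names = FALSE)
  if (!all(trait_order %in% flat))
    fs_stop("parameter_error", paste("unmapped trait(s):",
            paste(setdiff(trait_order, flat), collapse = ", ")))
  n <- length(trait_order)
  B <- matrix(0, n, n, dimnames = list(trait_order, trait_order))
  for (m in modules) {
    idx <- match(intersect(m, trait_order), trait_order)
    B[idx, idx] <- 1
  }
  diag(B) <- 0
  structure(list(criterion = criterion, modules = modules, pair_matrix = B),
            class = "module_hypothesis")
}

#' Mantel test of an empirical matrix against a hypothesis matrix
#'
#' The Mantel statistic is the Pearson correlation of the vectorized
#' lower-triangle off-diagonal entries of the two matrices. The null
#' distribution jointly permutes rows and columns of `B`; the one-tailed
#' p-value is \eqn{(\#\{r_{perm} \ge r_{obs}\} + 1)/(n_{perm} + 1)}
#' (the hypothesis predicts positive matrix association).
#'
#' @param A empirical matrix (`corr_matrix`, `floral_fixture`, or matrix).
#' @param B hypothesis matrix (`module_hypothesis` or matrix) with the same
#'   trait order.
#' @param n_perm permutations (default 999).
#' @param seed integer seed (required when `n_perm > 0`).
#' @return a `mantel_result` list: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = NULL) {
  a <- as_corr(A); b <- as_corr(B)
  stopifnot(identical(dim(a), dim(b)))
  va <- lower_vec(a); vb <- lower_vec(b)
  if (sd(va) == 0 || sd(vb) == 0)
    fs_stop("undefined_statistic_error",
            "zero variance in a vectorized matrix (is every trait in one module?)")
  r_obs <- cor(va, vb)
  p <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) fs_stop("parameter_error", "permutation test requires a seed")
    n <- nrow(b)
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      cor(va, lower_vec(b[pm, pm]))
    }, numeric(1)))
    p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm), class = "mantel_result")
}

#' Bootstrap CI for a Mantel statistic
#'
#' Resamples individuals with replacement, recomputes the empirical
#' correlation matrix and its Mantel correlation with the hypothesis matrix
#' each iteration, and takes the 2.5th/97.5th percentiles. Resamples in
#' which some trait has zero variance (or an undefined pairwise
#' correlation) are redrawn and counted.
#'
#' @param means an `individual_traits` table (raw individual-level data).
#' @param B a `module_hypothesis` (or 0/1 matrix).
#' @param traits trait columns.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list: `ci_low`, `ci_high`, `n_boot`, `n_redrawn`.
#' @export
mantel_bootstrap_ci <- function(means, B, traits = floral_traits(),
                                n_boot = 1000, seed = NULL, conf = 0.95) {
  if (is.null(seed)) fs_stop("parameter_error", "bootstrap requires a seed")
  X <- as.matrix(as.data.frame(means)[, traits, drop = FALSE])
  vb <- lower_vec(as_corr(B))
  n <- nrow(X)
  with_seed(seed, {
    stats <- numeric(n_boot)
    redrawn <- 0L
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        rm_ <- suppressWarnings(cor(X[idx, , drop = FALSE],
                                    use = "pairwise.complete.obs"))
        va <- lower_vec(rm_)
        if (!anyNA(va) && sd(va) > 0) break
        redrawn <- redrawn + 1L
      }
      stats[i] <- cor(va, vb)
    }
    a <- (1 - conf) / 2
    list(ci_low = unname(quantile(stats, a)),
         ci_high = unname(quantile(stats, 1 - a)),
         n_boot = n_boot, n_redrawn = redrawn)
  })
}

#' Eigenvalue-variance integration index
#'
#' Summarizes overall phenotypic integration as the dispersion of the
#' correlation-matrix eigenvalues: the more variance is concentrated in few
#' eigenvalues, the more integrated the trait set. Variants:
#' `raw` \eqn{= \sum (\lambda_i - 1)^2 / N} (range 0 to \eqn{N-1});
#' `relative` \eqn{= raw / (N - 1)} (range 0 to 1, equals the mean squared
#' off-diagonal correlation); `bias_corrected` \eqn{= raw - (N-1)/n}
#' (floored at 0), which removes the finite-sample expectation under
#' independence.
#'
#' @param M correlation matrix (`corr_matrix`, `floral_fixture`, or matrix).
#' @param variant headline variant (default `"relative"`).
#' @param n_individuals sample size (required for `bias_corrected`).
#' @return an `integration_index` list: `variant`, `value`, `all` (named
#'   vector of all variants), `eigenvalues`, `n_traits`, `n_individuals`.
#' @export
eigenvalue_variance <- function(M, variant = c("relative", "raw", "bias_corrected"),
                                n_individuals = NULL) {
  variant <- match.arg(variant)
  m <- as_corr(M)
  if (max(abs(m - t(m))) > 1e-8)
    fs_stop("parameter_error", "matrix must be symmetric")
  N <- nrow(m)
  lambda <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  raw <- sum((lambda - 1)^2) / N
  all <- c(raw = raw, relative = raw / (N - 1),
           bias_corrected = if (is.null(n_individuals)) NA_real_
                            else max(raw - (N - 1) / n_individuals, 0))
  if (variant == "bias_corrected" && is.null(n_individuals))
    fs_stop("parameter_error", "bias_corrected needs n_individuals")
  structure(list(variant = variant, value = unname(all[variant]), all = all,
                 eigenvalues = lambda, n_traits = N,
                 n_individuals = n_individuals),
            class = "integration_index")
}
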