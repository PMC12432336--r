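#' Run the full analysis pipeline
#'
#' Executes the stages in study order - data assembly, variation
#' (CV/PCA/variance partition), integration (correlation matrix, three
#' modularity Mantel tests, eigenvalue-variance index), mating-system GLM,
#' and selection (opportunity, differentials, screening, gradients) - from
#' one configuration, either on supplied CSV inputs or on a simulated data
#' set. Every stochastic step takes its seed from the config, so a rerun
#' with the same config is bit-reproducible. If only a printed correlation
#' matrix is available (`matrix_path`), the matrix-level integration
#' analyses run and the stages needing raw data are skipped with logged
#' reasons.
#'
#' @param cfg a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{simulate}{list of [sim_config()] arguments plus `seed`, or
#'       `NULL`}
#'     \item{flowers_path, fitness_path, pollination_path}{CSV inputs,
#'       used when `simulate` is absent}
#'     \item{matrix_path}{triangular-CSV correlation matrix for
#'       matrix-only mode}
#'     \item{n_perm, n_boot}{resampling sizes (defaults 999, 1000)}
#'     \item{seed}{base seed for resampling stages (default 1)}
#'     \item{out_dir}{optional output directory for CSV/JSON results and
#'       a markdown report}
#'   }
#' @return a `run_report` list with per-stage results, a `decisions` log,
#'   the echoed config, and the package version.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  n_perm <- cfg$n_perm %||% 999
  n_boot <- cfg$n_boot %||% 1000
  seed <- cfg$seed %||% 1L
  if (n_perm < 99 || n_boot < 99)
    fs_stop("parameter_error", "resampling counts must be >= 99")
  decisions <- character(0)
  note <- function(...) decisions <<- c(decisions, sprintf(...))
  res <- list()

  matrix_only <- !is.null(cfg$matrix_path) && is.null(cfg$simulate) &&
    is.null(cfg$flowers_path)
  if (matrix_only) {
    m <- read_lower_triangle_matrix(cfg$matrix_path)
    res$integration <- integration_stage_matrix(m, n_individuals = cfg$n_individuals %||% NA,
                                                n_perm = n_perm, seed = seed)
    for (st in c("variation", "mating_system", "selection"))
      note("skip %s: raw data unavailable in matrix-only mode", st)
  } else {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_seed <- sim_args$seed %||% seed
      sim_args$seed <- NULL
      scfg <- do.call(sim_config, sim_args)
      dat <- simulate_dataset(scfg, seed = sim_seed)
      note("data simulated (n_individuals = %d, seed = %d)",
           scfg$n_individuals, as.integer(sim_seed))
    } else {
      dat <- list(flowers = read_flower_table(cfg$flowers_path))
      dat$means <- suppressWarnings(aggregate_individual_means(dat$flowers))
      dat$fitness <- read_fitness_table(cfg$fitness_path)
      dat$pollination <- if (!is.null(cfg$pollination_path))
        read_pollination_table(cfg$pollination_path) else NULL
    }
    lr <- attr(dat$flowers, "load_report")
    if (!is.null(lr) && lr$n_flagged_values > 0)
      note("%d trait value(s) flagged missing at load", lr$n_flagged_values)

    joined <- filter_for_selection(dat$means, dat$fitness)
    jr <- attr(joined, "join_report")
    note("selection set: %d joined, %d trait-only, %d fitness-only excluded",
         jr$n_joined, jr$n_traits_only, jr$n_fitness_only)
    multi <- filter_multiflower(dat$flowers)
    note("multi-flower subset: %d single-flower individual(s) excluded",
         attr(multi, "n_dropped_individuals"))

    # variation
    means_joined <- joined[, c("individual_id", "n_flowers", floral_traits())]
    class(means_joined) <- c("individual_traits", "data.frame")
    res$variation <- list(
      cv = cv_table(means_joined),
      pca = if (nrow(multi) >= 2) pca_standardized(multi) else NULL,
      varpart = if (nrow(multi) > 0) variance_partition_table(multi) else NULL)
    if (nrow(multi) == 0)
      note("skip PCA/variance partition: no multi-flower individuals")

    # integration
    corr <- pearson_matrix(means_joined, n_boot = n_boot, seed = seed + 10L)
    mant <- lapply(c("morphological", "functional", "developmental"), function(cr) {
      B <- hypothesis_matrix(cr)
      mt <- mantel_test(corr, B, n_perm = n_perm, seed = seed + 20L)
      ci <- mantel_bootstrap_ci(means_joined, B, n_boot = n_boot, seed = seed + 30L)
      list(criterion = cr, r = mt$r, p = mt$p, ci_low = ci$ci_low,
           ci_high = ci$ci_high)
    })
    names(mant) <- vapply(mant, `[[`, "", "criterion")
    res$integration <- list(
      corr = corr, mantel = mant,
      index = eigenvalue_variance(corr, n_individuals = nrow(means_joined)))

    # mating system
    if (!is.null(dat$pollination)) {
      full <- fit_cloglog_binomial(dat$pollination)
      null <- fit_cloglog_binomial(dat$pollination, ~ 1)
      for (tr in names(full$boundary)[full$boundary])
        note("boundary fruit-set estimate for treatment %s", tr)
      res$mating_system <- list(
        fit = full,
        test = treatment_effect_test(null, full),
        pairwise = pairwise_comparisons(full, seed = seed + 40L))
    } else note("skip mating_system: no pollination table")

    # selection
    design <- make_design(joined)
    S <- selection_differentials(design)
    sel <- list(design_n = design$n,
                opportunity = opportunity_of_selection(design, n_boot = n_boot,
                                                       seed = seed + 50L),
                differentials = S)
    if (!is.null(res$variation$varpart)) {
      subset <- tryCatch(
        screen_traits(res$variation$varpart, corr, S = S),
        floralsel_error = function(e) { note("screening failed: %s",
                                             conditionMessage(e)); NULL })
      if (!is.null(subset)) {
        for (msg in attr(subset, "log")) note("screen: %s", msg)
        if (length(subset) >= 2) {
          sel$subset <- as.character(subset)
          sel$gradients <- tryCatch(
            selection_gradients(design, subset),
            floralsel_error = function(e) {
              note("skip gradients: %s", conditionMessage(e)); NULL })
        } else note("skip gradients: fewer than 2 traits survive screening")
      }
    } else note("skip screening: no variance partition available")
    res$selection <- sel
  }

  report <- structure(list(results = res, decisions = decisions, config = cfg,
                           version = as.character(packageVersion("floralsel"))),
                      class = "run_report")
  if (!is.null(cfg$out_dir)) write_run_report(report, cfg$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

integration_stage_matrix <- function(m, n_individuals = NA, n_perm = 999, seed = 1L) {
  mant <- lapply(c("morphological", "functional", "developmental"), function(cr) {
    mt <- mantel_test(m, hypothesis_matrix(cr), n_perm = n_perm, seed = seed)
    list(criterion = cr, r = mt$r, p = mt$p)
  })
  names(mant) <- vapply(mant, `[[`, "", "criterion")
  list(corr = m, mantel = mant,
       index = eigenvalue_variance(m, n_individuals =
                                     if (is.na(n_individuals)) NULL else n_individuals))
}

#' Write a run report to disk
#'
#' One CSV/JSON file per stage plus a human-readable `report.md`. Numbers
#' are written at full precision; the markdown report rounds for display
#' (2 decimals for correlations, 1 for percentages).
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  put_csv <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(res$variation)) {
    put_csv(res$variation$cv, "cv.csv")
    if (!is.null(res$variation$varpart)) put_csv(res$variation$varpart, "variance_partition.csv")
    if (!is.null(res$variation$pca)) {
      put_csv(data.frame(trait = rownames(res$variation$pca$loadings),
                         res$variation$pca$loadings, check.names = FALSE),
              "pca_loadings.csv")
      put_csv(data.frame(trait = rownames(res$variation$pca$contributions_pct),
                         res$variation$pca$contributions_pct, check.names = FALSE),
              "pca_contributions.csv")
    }
  }
  if (!is.null(res$integration)) {
    cm <- as_corr(res$integration$corr)
    write_lower_triangle_matrix(cm, file.path(out_dir, "correlation_matrix.csv"),
                                digits = 6)
    mant_df <- do.call(rbind, lapply(res$integration$mantel, function(m)
      data.frame(criterion = m$criterion, r = m$r, p = m$p,
                 ci_low = m$ci_low %||% NA, ci_high = m$ci_high %||% NA)))
    put_csv(mant_df, "mantel.csv")
    jsonlite::write_json(res$integration$index$all,
                         file.path(out_dir, "integration_index.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$mating_system)) {
    put_csv(res$mating_system$pairwise$table, "pairwise_contrasts.csv")
    ms <- res$mating_system
    jsonlite::write_json(list(
      dispersion = ms$fit$dispersion, deviance = ms$fit$deviance,
      fitted = as.list(ms$fit$fitted), observed = as.list(ms$fit$observed),
      boundary = as.list(ms$fit$boundary),
      lrt = list(statistic = ms$test$statistic, df = ms$test$df, p = ms$test$p,
                 f_statistic = ms$test$f_statistic, p_f = ms$test$p_f),
      letters = as.list(ms$pairwise$letters)),
      file.path(out_dir, "mating_system.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$selection)) {
    put_csv(res$selection$differentials, "selection_differentials.csv")
    if (!is.null(res$selection$gradients)) {
      put_csv(res$selection$gradients$linear, "selection_gradients_linear.csv")
      put_csv(res$selection$gradients$quadratic, "selection_gradients_quadratic.csv")
      put_csv(res$selection$gradients$correlational, "selection_gradients_correlational.csv")
    }
    op <- res$selection$opportunity
    jsonlite::write_json(list(I = op$I, se = op$se, n = op$n),
                         file.path(out_dir, "opportunity.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  md <- c("# Analysis report", "",
          sprintf("floralsel %s", report$version), "", "## Decisions", "",
          paste("-", report$decisions))
  if (!is.null(res$integration)) {
    md <- c(md, "", "## Modularity (Mantel)", "",
            vapply(res$integration$mantel, function(m)
              sprintf("- %s: r = %.2f%s", m$criterion, m$r,
                      if (is.na(m$p)) "" else sprintf(", p = %.3f", m$p)),
              character(1)),
            sprintf("- integration index (relative) = %.3f",
                    res$integration$index$all["relative"]))
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Matrix-level analyses of the packaged published-summary fixture
#'
#' Runs everything the printed summary table supports: the three modularity
#' Mantel statistics against the published 10-trait correlation matrix,
#' per-trait counts of significant correlations (two-sided t-test at the
#' published sample size), PC1/PC2 variable contributions recomputed from
#' the printed loadings, and the eigenvalue-variance integration index.
#' This is the package's reproducibility entry point for the published
#' results.
#'
#' @param n_perm Mantel permutations (0 skips the permutation p-value).
#' @param seed seed for the permutation test.
#' @param alpha significance level for correlation counts.
#' @return a `fixture_report` list: `mantel` (per criterion: `r`,
#'   `r_rounded`, `p`), `sig_counts` (named per-trait counts),
#'   `contributions` (traits x PC1/PC2, percent), `index` (named vector of
#'   integration-index variants), `n`.
#' @export
#' @examples
#' rep <- fixture_report(n_perm = 0)
#' rep$mantel$morphological$r_rounded  # 0.29
fixture_report <- function(n_perm = 999, seed = 1L, alpha = 0.05) {
  fx <- table1_fixture()
  mant <- lapply(c("morphological", "functional", "developmental"), function(cr) {
    mt <- mantel_test(fx$corr, hypothesis_matrix(cr),
                      n_perm = n_perm, seed = if (n_perm > 0) seed else NULL)
    list(criterion = cr, r = mt$r, r_rounded = round(mt$r, 2), p = mt$p)
  })
  names(mant) <- vapply(mant, `[[`, "", "criterion")

  # significance of each printed r at the published n, two-sided t-test
  r <- fx$corr
  tval <- r * sqrt(fx$n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tval), fx$n - 2)
  diag(p) <- NA
  sig_counts <- colSums(p < alpha, na.rm = TRUE)

  L <- as.matrix(fx$summary[, c("pc1", "pc2")])
  rownames(L) <- fx$summary$trait
  contrib <- pca_contributions(L)
  colnames(contrib) <- c("PC1", "PC2")

  idx <- eigenvalue_variance(fx$corr, n_individuals = fx$n)

  structure(list(mantel = mant, sig_counts = sig_counts,
                 contributions = contrib, index = idx$all, n = fx$n),
            class = "fixture_report")
}
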