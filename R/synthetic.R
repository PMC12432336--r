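#' Module specification for a block correlation structure
#'
#' Partitions the trait set into named modules and sets the target Pearson
#' correlation for same-module and different-module trait pairs. Used both
#' to generate data with known modular structure and as the ground truth
#' when testing the modularity machinery.
#'
#' @param modules named list of character vectors partitioning the traits.
#' @param within_module_r target correlation for same-module pairs, in (-1, 1).
#' @param between_module_r target correlation for different-module pairs.
#' @param trait_order full trait set; every trait must appear in exactly one
#'   module.
#' @return a `module_spec` list.
#' @export
module_spec <- function(modules, within_module_r = 0.4, between_module_r = 0,
                        trait_order = floral_traits()) {
  if (abs(within_module_r) >= 1 || abs(between_module_r) >= 1)
    fs_stop("parameter_error", "module correlations must lie in (-1, 1)")
  flat <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, trait_order))
    fs_stop("parameter_error", "modules must partition the trait set exactly")
  structure(list(modules = modules, within_module_r = within_module_r,
                 between_module_r = between_module_r,
                 trait_order = trait_order),
            class = "module_spec")
}

#' Build the target block correlation matrix
#'
#' Unit diagonal; `within_module_r` for same-module pairs and
#' `between_module_r` otherwise. If the block pattern is not positive
#' semidefinite (e.g. equicorrelation below \eqn{-1/(N-1)}), negative
#' eigenvalues are clipped at zero and the matrix re-normalized to unit
#' diagonal; the `clipped` attribute records whether that happened.
#'
#' @param spec a [module_spec()].
#' @param trait_order trait order for rows/columns.
#' @return correlation matrix with attribute `clipped` (logical).
#' @export
build_block_correlation <- function(spec, trait_order = spec$trait_order) {
  n <- length(trait_order)
  m <- matrix(spec$between_module_r, n, n, dimnames = list(trait_order, trait_order))
  for (mod in spec$modules) {
    idx <- match(mod, trait_order)
    m[idx, idx] <- spec$within_module_r
  }
  diag(m) <- 1
  e <- eigen(m, symmetric = TRUE)
  clipped <- any(e$values < -1e-12)
  if (clipped) {
    v <- pmax(e$values, 0)
    m <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
    dimnames(m) <- list(trait_order, trait_order)
  }
  attr(m, "clipped") <- clipped
  m
}

#' Selection surface acting on standardized traits
#'
#' Expected relative fitness is the quadratic approximation
#' \eqn{w(z) = 1 + \beta' z + z' \gamma z / 2} on standardized trait values,
#' truncated below at `eps` so fitness stays positive under strong
#' curvature. `beta` holds directional (linear) gradients; the diagonal of
#' `gamma` holds quadratic (stabilizing/disruptive) gradients and its
#' off-diagonal the correlational gradients.
#'
#' @param beta named numeric vector of linear gradients (traits absent
#'   default to 0).
#' @param gamma symmetric matrix of quadratic/correlational gradients, or a
#'   named vector interpreted as its diagonal; defaults to all zero.
#' @param p0 baseline fruit-set probability at the phenotypic mean.
#' @param eps positive floor applied to \eqn{w(z)}.
#' @param trait_order trait set the surface is defined over.
#' @return a `selection_surface` list.
#' @export
selection_surface <- function(beta = NULL, gamma = NULL, p0 = 0.15,
                              eps = 1e-6, trait_order = floral_traits()) {
  n <- length(trait_order)
  b <- setNames(numeric(n), trait_order)
  if (!is.null(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% trait_order))
      fs_stop("parameter_error", "beta must be named by traits")
    b[names(beta)] <- beta
  }
  g <- matrix(0, n, n, dimnames = list(trait_order, trait_order))
  if (!is.null(gamma)) {
    if (is.matrix(gamma)) {
      if (!isTRUE(all.equal(gamma, t(gamma))))
        fs_stop("parameter_error", "gamma must be symmetric")
      g[rownames(gamma), colnames(gamma)] <- gamma
    } else {
      diag(g)[match(names(gamma), trait_order)] <- gamma
    }
  }
  if (p0 <= 0 || p0 >= 1) fs_stop("parameter_error", "p0 must lie in (0, 1)")
  structure(list(beta = b, gamma = g, p0 = p0, eps = eps,
                 trait_order = trait_order),
            class = "selection_surface")
}

#' Simulation configuration
#'
#' Describes the population the generator emulates. Defaults mirror the
#' study system: ten traits with the published means and SDs, one to three
#' flowers measured per individual, and six pollination treatments with the
#' observed fruit-set rates (0, 2.2, 5.6, 33.3, 42.9 and 19.1 per cent) at
#' the field sample sizes (90, 90, 90, 90, 191, 178 flowers).
#'
#' @param n_individuals number of plants.
#' @param flowers_min,flowers_max range of flowers measured per individual;
#'   counts are drawn uniformly over `flowers_min:flowers_max`.
#' @param trait_means,trait_sds named per-trait population mean and total SD
#'   (mm); defaults are the published values.
#' @param within_fraction per-trait fraction of total variance that lies
#'   within individuals (flower-to-flower), in \[0, 1); scalar recycled.
#' @param modules a [module_spec()] for the among-individual correlation.
#' @param surface a [selection_surface()].
#' @param flowers_counted flowers censused per plant for the fitness ratio
#'   (scalar or vector).
#' @param treatment_p named success probabilities for the six pollination
#'   treatments.
#' @param treatment_n named flower totals per treatment.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 90,
                       flowers_min = 1, flowers_max = 3,
                       trait_means = NULL, trait_sds = NULL,
                       within_fraction = 0.3,
                       modules = NULL,
                       surface = selection_surface(),
                       flowers_counted = 30,
                       treatment_p = c(spontaneous_self = 0, manual_self = 0.022,
                                       geitonogamy = 0.056, cross = 0.333,
                                       supplementation = 0.429, natural = 0.191),
                       treatment_n = c(spontaneous_self = 90, manual_self = 90,
                                       geitonogamy = 90, cross = 90,
                                       supplementation = 191, natural = 178)) {
  traits <- floral_traits()
  if (is.null(trait_means))
    trait_means <- setNames(c(13.8, 6.4, 32.8, 30.9, 6.7, 29.8, 6.4, 1.4, 1.4, 31.7), traits)
  if (is.null(trait_sds))
    trait_sds <- setNames(c(5.7, 0.4, 1.8, 2.0, 0.6, 1.7, 2.3, 0.2, 0.1, 2.3), traits)
  if (is.null(modules))
    modules <- module_spec(list(
      calyx = traits[1:2], corolla = traits[3:5],
      androecium = traits[6:7], gynoecium = traits[8:10]))
  wf <- rep_len(within_fraction, length(traits))
  if (any(wf < 0 | wf >= 1))
    fs_stop("parameter_error", "within_fraction must lie in [0, 1)")
  if (any(treatment_p < 0 | treatment_p > 1))
    fs_stop("parameter_error", "treatment probabilities must lie in [0, 1]")
  structure(list(n_individuals = n_individuals,
                 flowers_min = flowers_min, flowers_max = flowers_max,
                 trait_means = trait_means[traits], trait_sds = trait_sds[traits],
                 within_fraction = setNames(wf, traits),
                 modules = modules, surface = surface,
                 flowers_counted = flowers_counted,
                 treatment_p = treatment_p, treatment_n = treatment_n),
            class = "sim_config")
}

#' Simulate flower-level trait measurements
#'
#' Each individual gets a latent trait vector drawn from a multivariate
#' normal with the block correlation of `cfg$modules` and per-trait SD
#' \eqn{\sigma \sqrt{1 - f}} (the among-individual share); each measured
#' flower adds independent normal noise with SD \eqn{\sigma \sqrt{f}}
#' (the within-individual share). Deterministic given `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (required).
#' @return a `flower_table` with attribute `latent` holding the individual
#'   latent trait matrix (ground truth for oracle checks).
#' @export
simulate_traits <- function(cfg, seed) {
  traits <- floral_traits()
  R <- build_block_correlation(cfg$modules, traits)
  sd_among <- cfg$trait_sds * sqrt(1 - cfg$within_fraction)
  sd_within <- cfg$trait_sds * sqrt(cfg$within_fraction)
  Sigma <- diag(sd_among) %*% R %*% diag(sd_among)
  with_seed(seed, {
    n <- cfg$n_individuals
    latent <- MASS::mvrnorm(n, mu = cfg$trait_means, Sigma = Sigma)
    colnames(latent) <- traits
    rownames(latent) <- sprintf("ind_%03d", seq_len(n))
    k_levels <- seq(cfg$flowers_min, cfg$flowers_max)
    k <- if (length(k_levels) == 1L) rep(k_levels, n)
         else sample(k_levels, n, replace = TRUE)
    rows <- rep(seq_len(n), k)
    noise <- matrix(rnorm(length(rows) * length(traits)), ncol = length(traits))
    noise <- sweep(noise, 2, sd_within, `*`)
    vals <- latent[rows, , drop = FALSE] + noise
    vals[vals <= 0] <- NA_real_  # physically impossible measurements flagged
    out <- data.frame(individual_id = rownames(latent)[rows],
                      flower_id = unlist(lapply(k, seq_len)))
    out <- cbind(out, as.data.frame(vals))
    rownames(out) <- NULL
    out <- as_flower_table(out)
    attr(out, "latent") <- latent
    out
  })
}

#' Expected relative fitness under a selection surface
#' @param z matrix of standardized trait values (individuals x traits).
#' @param surf a [selection_surface()].
#' @return numeric vector \eqn{\max(w(z), eps)}.
#' @export
surface_fitness <- function(z, surf) {
  z <- as.matrix(z[, surf$trait_order, drop = FALSE])
  w <- 1 + drop(z %*% surf$beta) + 0.5 * rowSums((z %*% surf$gamma) * z)
  pmax(w, surf$eps)
}

#' Simulate binomial fruit-set fitness from a selection surface
#'
#' Trait means are standardized internally, expected relative fitness
#' \eqn{w(z)} is mapped to a per-individual fruit-set probability
#' \eqn{p_i = \min(\max(p_0 w(z_i), 0), 1)}, and fruit counts are drawn
#' binomially from the censused flowers. Deterministic given `seed`.
#'
#' @param means an `individual_traits` table (complete cases used).
#' @param surf a [selection_surface()]; defaults to `cfg$surface`.
#' @param cfg a [sim_config()] (for `flowers_counted`).
#' @param seed integer seed.
#' @return fitness data.frame: `individual_id`, `flowers_counted`,
#'   `fruits_counted`, `W`.
#' @export
simulate_fitness <- function(means, cfg, seed, surf = cfg$surface) {
  traits <- surf$trait_order
  z <- scale(as.matrix(means[, traits, drop = FALSE]))
  z[is.na(z)] <- 0  # missing trait means carry no selection signal
  w <- surface_fitness(z, surf)
  if (all(w <= surf$eps))
    fs_stop("degenerate_surface_error", "expected fitness non-positive everywhere")
  p <- pmin(pmax(surf$p0 * w, 0), 1)
  fl <- rep_len(cfg$flowers_counted, nrow(means))
  with_seed(seed, {
    fruits <- rbinom(length(p), size = fl, prob = p)
    data.frame(individual_id = means$individual_id,
               flowers_counted = fl, fruits_counted = fruits,
               W = fruits / fl)
  })
}

#' Simulate a pollination experiment
#'
#' For each treatment the configured flower total is spread over simulated
#' individuals (one flower each for the bagged treatments, one to three for
#' supplementation/natural, mirroring the field design) and fruit counts are
#' drawn binomially at the treatment success probability.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return validated pollination data.frame (see [as_pollination_table()]).
#' @export
simulate_pollination <- function(cfg, seed) {
  with_seed(seed, {
    out <- lapply(names(cfg$treatment_p), function(tr) {
      n_total <- cfg$treatment_n[[tr]]
      max_per <- if (tr %in% c("supplementation", "natural")) 3L else 1L
      counts <- integer(0)
      while (sum(counts) < n_total) {
        counts <- c(counts, sample.int(max_per, 1L))
      }
      counts[length(counts)] <- counts[length(counts)] - (sum(counts) - n_total)
      counts <- counts[counts > 0]
      data.frame(treatment = tr,
                 individual_id = sprintf("%s_%03d", tr, seq_along(counts)),
                 n_flowers = counts,
                 n_fruits = rbinom(length(counts), counts, cfg$treatment_p[[tr]]))
    })
    as_pollination_table(do.call(rbind, out))
  })
}

#' Simulate a complete study data set
#'
#' Convenience wrapper producing the three tables every stage consumes:
#' flower-level traits, per-individual fitness, and the pollination
#' experiment. Sub-seeds are derived deterministically from `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `flowers`, `means`, `fitness`, `pollination`.
#' @export
simulate_dataset <- function(cfg, seed) {
  flowers <- simulate_traits(cfg, seed = seed)
  means <- suppressWarnings(aggregate_individual_means(flowers))
  fitness <- simulate_fitness(means, cfg, seed = seed + 1L)
  pollination <- simulate_pollination(cfg, seed = seed + 2L)
  list(flowers = flowers, means = means, fitness = fitness,
       pollination = pollination)
}
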