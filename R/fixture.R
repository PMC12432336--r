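#' Packaged published-summary fixture
#'
#' The package ships a transcription of the published population summary for
#' the ten floral traits: per-trait mean, SD, CV with 95% CI, loadings on the
#' first two principal components, and the 10 x 10 Pearson correlation matrix
#' (2-decimal precision) with per-pair bootstrap CI bounds and significance
#' flags. Raw field measurements were not deposited, so this fixture is the
#' only real-data entry point; matrix-level analyses (Mantel tests,
#' eigenvalue-variance indices, PCA contributions from loadings) run directly
#' on it via [fixture_report()].
#'
#' @param n_individuals sample size behind the printed matrix (81
#'   individuals with both trait and fitness data).
#' @return a list of class `floral_fixture`:
#'   \describe{
#'     \item{summary}{data.frame of per-trait mean/SD/CV/CI/PC loadings}
#'     \item{corr}{10 x 10 symmetric correlation matrix, unit diagonal}
#'     \item{ci_low, ci_high}{symmetric matrices of per-pair CI bounds}
#'     \item{significant}{logical symmetric matrix of published
#'       significance flags}
#'     \item{n}{`n_individuals`}
#'   }
#' @export
#' @examples
#' fx <- table1_fixture()
#' fx$corr["style_length", "filament_length"]  # 0.50
table1_fixture <- function(n_individuals = 81L) {
  ext <- function(f) system.file("extdata", f, package = "floralsel", mustWork = TRUE)
  traits <- floral_traits()
  sm <- read.csv(ext("morphometry_summary.csv"), stringsAsFactors = FALSE)
  stopifnot(identical(sm$trait, traits))
  corr <- read_lower_triangle_matrix(ext("correlation_matrix.csv"), traits)

  ci <- read.csv(ext("correlation_ci.csv"), stringsAsFactors = FALSE)
  lo <- hi <- matrix(NA_real_, 10, 10, dimnames = list(traits, traits))
  diag(lo) <- diag(hi) <- 1
  for (k in seq_len(nrow(ci))) {
    i <- ci$trait_row[k]; j <- ci$trait_col[k]
    lo[i, j] <- lo[j, i] <- ci$ci_low[k]
    hi[i, j] <- hi[j, i] <- ci$ci_high[k]
  }

  sig <- matrix(FALSE, 10, 10, dimnames = list(traits, traits))
  sg <- read.csv(ext("correlation_significant.csv"), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(sg))) {
    sig[sg$trait_row[k], sg$trait_col[k]] <- TRUE
    sig[sg$trait_col[k], sg$trait_row[k]] <- TRUE
  }

  structure(list(summary = sm, corr = corr, ci_low = lo, ci_high = hi,
                 significant = sig, n = as.integer(n_individuals)),
            class = "floral_fixture")
}
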