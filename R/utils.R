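#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards, so seeded package operations never
#' perturb global random state. A `NULL` seed evaluates `code` unseeded.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Extract lower-triangle off-diagonal entries in column order
#' @param m square matrix
#' @return numeric vector of length `n * (n - 1) / 2`
#' @keywords internal
lower_vec <- function(m) m[lower.tri(m)]

# stop() with a classed condition so callers can test error categories
fs_stop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "floralsel_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
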