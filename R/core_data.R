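#' Canonical floral trait order
#'
#' The ten external floral measurements used throughout the package, in the
#' fixed order that every matrix and coefficient vector indexes by:
#' calyx (sepal length/width), corolla (corolla width, tube length/width),
#' androecium (filament and anther length), gynoecium (ovary length/width,
#' style length). All measurements are in millimetres.
#'
#' @return character vector of length 10.
#' @export
#' @examples
#' floral_traits()
floral_traits <- function() {
  c("sepal_length", "sepal_width", "corolla_width", "tube_length",
    "tube_width", "filament_length", "anther_length", "ovary_length",
    "ovary_width", "style_length")
}

#' Read a flower-level morphometric table
#'
#' Reads a CSV with one row per measured flower: an `individual_id`, a
#' `flower_id` unique within individual, and one numeric column per floral
#' trait (mm). Trait values must be strictly positive; non-positive or
#' unparseable values are set to `NA` and counted in the load report
#' (attribute `"load_report"`).
#'
#' @param path path to a CSV file with a header row.
#' @param traits trait column names expected; defaults to [floral_traits()].
#' @param schema optional named character vector mapping file column names
#'   to canonical names, e.g. `c(plant = "individual_id")`.
#' @return a `flower_table`: a data.frame with columns `individual_id`,
#'   `flower_id` and the trait columns, plus attribute `load_report`
#'   (list with `n_rows`, `n_flagged_values`, `n_rows_flagged`).
#' @export
read_flower_table <- function(path, traits = floral_traits(), schema = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    hit <- match(names(schema), names(raw))
    if (anyNA(hit)) fs_stop("schema_error", "schema names a column absent from the file")
    names(raw)[hit] <- unname(schema)
  }
  as_flower_table(raw, traits = traits)
}

#' Validate a data.frame as a flower table
#'
#' @param x data.frame with `individual_id`, `flower_id` and trait columns.
#' @inheritParams read_flower_table
#' @return a validated `flower_table` (see [read_flower_table()]).
#' @export
as_flower_table <- function(x, traits = floral_traits()) {
  need <- c("individual_id", "flower_id", traits)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    fs_stop("schema_error", paste("missing mandatory columns:",
                                  paste(missing_cols, collapse = ", ")))
  x <- as.data.frame(x)[, need]
  key <- paste(x$individual_id, x$flower_id, sep = "\r")
  if (anyDuplicated(key))
    fs_stop("integrity_error", "duplicate (individual_id, flower_id) key")
  n_flagged <- 0L
  flagged_row <- rep(FALSE, nrow(x))
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(x[[tr]]))
    bad <- !is.na(x[[tr]]) & (is.na(v) | v <= 0)
    v[bad] <- NA_real_
    n_flagged <- n_flagged + sum(bad)
    flagged_row <- flagged_row | bad
    x[[tr]] <- v
  }
  attr(x, "load_report") <- list(n_rows = nrow(x),
                                 n_flagged_values = n_flagged,
                                 n_rows_flagged = sum(flagged_row))
  class(x) <- c("flower_table", "data.frame")
  x
}

#' Per-individual trait means
#'
#' Collapses a flower table to one row per individual: the arithmetic mean
#' of each trait over that individual's flowers, ignoring missing values,
#' plus the flower count. An individual with no usable value for a trait
#' gets `NA` there, with a warning.
#'
#' @param t a `flower_table`.
#' @param traits trait columns to aggregate.
#' @return an `individual_traits` data.frame: `individual_id`, `n_flowers`,
#'   and one mean column per trait (mm).
#' @export
aggregate_individual_means <- function(t, traits = floral_traits()) {
  stopifnot(nrow(t) > 0)
  ids <- unique(t$individual_id)
  out <- data.frame(individual_id = ids,
                    n_flowers = as.integer(table(t$individual_id)[as.character(ids)]))
  for (tr in traits)
    out[[tr]] <- vapply(ids, function(id) {
      v <- t[[tr]][t$individual_id == id]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  if (anyNA(out[traits]))
    warning("some individuals have no usable value for one or more traits")
  rownames(out) <- NULL
  class(out) <- c("individual_traits", "data.frame")
  out
}

#' Keep only individuals with at least two measured flowers
#'
#' Variance partitioning (and flower-level PCA) needs within-individual
#' replication, so single-flower individuals are dropped; all flower-level
#' rows of the retained individuals are kept.
#'
#' @param t a `flower_table`.
#' @return a `flower_table` (possibly empty) with an `n_dropped_individuals`
#'   attribute.
#' @export
filter_multiflower <- function(t) {
  counts <- table(t$individual_id)
  keep <- names(counts)[counts >= 2]
  out <- t[as.character(t$individual_id) %in% keep, , drop = FALSE]
  attr(out, "n_dropped_individuals") <- sum(counts < 2)
  attr(out, "load_report") <- attr(t, "load_report")
  class(out) <- class(t)
  out
}

#' Join trait means with fitness for the selection analysis set
#'
#' Inner join of per-individual trait means and fitness counts on
#' `individual_id`. Only individuals present in both tables enter the
#' selection analyses; the counts excluded from each side are recorded in
#' the `join_report` attribute so the exclusion ledger is explicit.
#'
#' @param traits an `individual_traits` table.
#' @param fit a fitness data.frame with columns `individual_id`,
#'   `flowers_counted`, `fruits_counted` (and optionally `W`; recomputed
#'   as `fruits_counted / flowers_counted` regardless).
#' @return joined data.frame with trait means, `n_flowers`,
#'   `flowers_counted`, `fruits_counted` and `W`; attribute `join_report`
#'   lists `n_traits_only`, `n_fitness_only`, `n_joined`.
#' @export
filter_for_selection <- function(traits, fit) {
  stopifnot(all(c("individual_id", "flowers_counted", "fruits_counted") %in% names(fit)))
  if (any(fit$fruits_counted > fit$flowers_counted))
    fs_stop("integrity_error", "fruits_counted exceeds flowers_counted")
  common <- intersect(traits$individual_id, fit$individual_id)
  if (length(common) == 0L)
    fs_stop("empty_analysis_error",
            "no individuals have both trait and fitness data")
  tt <- traits[match(common, traits$individual_id), , drop = FALSE]
  ff <- fit[match(common, fit$individual_id), , drop = FALSE]
  out <- cbind(tt, ff[, c("flowers_counted", "fruits_counted"), drop = FALSE])
  out$W <- out$fruits_counted / out$flowers_counted
  rownames(out) <- NULL
  attr(out, "join_report") <- list(
    n_traits_only = length(setdiff(traits$individual_id, common)),
    n_fitness_only = length(setdiff(fit$individual_id, common)),
    n_joined = length(common))
  out
}

#' Read a lower-triangle correlation matrix file
#'
#' The triangular CSV dialect used for printed correlation tables: one row
#' per trait in fixed order; the first field is the trait name, followed by
#' the correlations with the traits that precede it (so the first row has
#' no values). Values are expanded into a symmetric matrix with unit
#' diagonal; 2-decimal printed values are preserved exactly.
#'
#' @param path path to the triangular CSV (no header).
#' @param trait_order expected trait order; defaults to [floral_traits()].
#' @return symmetric numeric matrix with `trait_order` dimnames.
#' @export
read_lower_triangle_matrix <- function(path, trait_order = floral_traits()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(trait_order)
  if (length(lines) != n)
    fs_stop("format_error", sprintf("expected %d rows, found %d", n, length(lines)))
  m <- diag(n)
  dimnames(m) <- list(trait_order, trait_order)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (trimws(parts[1]) != trait_order[i])
      fs_stop("format_error", sprintf("row %d is '%s', expected '%s'",
                                      i, trimws(parts[1]), trait_order[i]))
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (length(vals) != i - 1L || anyNA(vals))
      fs_stop("format_error", sprintf("row %d: expected %d numeric values", i, i - 1L))
    if (i > 1L) {
      m[i, seq_len(i - 1L)] <- vals
      m[seq_len(i - 1L), i] <- vals
    }
  }
  m
}

#' Write a correlation matrix in the lower-triangle dialect
#'
#' @param m symmetric matrix with dimnames.
#' @param path output file path.
#' @param digits decimal places written (default 2, the printed precision).
#' @return `path`, invisibly.
#' @export
write_lower_triangle_matrix <- function(m, path, digits = 2) {
  tr <- rownames(m)
  lines <- vapply(seq_along(tr), function(i) {
    vals <- if (i > 1) formatC(m[i, seq_len(i - 1)], format = "f",
                               digits = digits) else character(0)
    paste(c(tr[i], vals), collapse = ",")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-individual fitness table
#'
#' @param path CSV with columns `individual_id`, `flowers_counted`,
#'   `fruits_counted`.
#' @return data.frame with those columns plus `W = fruits / flowers`.
#' @export
read_fitness_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "flowers_counted", "fruits_counted")
  if (!all(need %in% names(x)))
    fs_stop("schema_error", "fitness table requires individual_id, flowers_counted, fruits_counted")
  if (any(x$fruits_counted > x$flowers_counted) || any(x$flowers_counted < 0))
    fs_stop("integrity_error", "invalid flower/fruit counts")
  x$W <- ifelse(x$flowers_counted > 0, x$fruits_counted / x$flowers_counted, NA_real_)
  x
}

#' Read a pollination-experiment table
#'
#' @param path CSV with columns `treatment`, `individual_id`, `n_flowers`,
#'   `n_fruits`. Treatments must come from the closed six-level set
#'   returned by [pollination_treatments()].
#' @return validated data.frame with `treatment` as a factor in canonical
#'   level order.
#' @export
read_pollination_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  as_pollination_table(x)
}

#' The six pollination treatment levels
#' @return character vector in canonical order.
#' @export
pollination_treatments <- function() {
  c("spontaneous_self", "manual_self", "geitonogamy", "cross",
    "supplementation", "natural")
}

#' Validate a pollination table
#' @param x data.frame with `treatment`, `individual_id`, `n_flowers`,
#'   `n_fruits`.
#' @return validated data.frame; `treatment` becomes a factor over
#'   [pollination_treatments()] levels (unused levels dropped).
#' @export
as_pollination_table <- function(x) {
  need <- c("treatment", "individual_id", "n_flowers", "n_fruits")
  if (!all(need %in% names(x)))
    fs_stop("schema_error", "pollination table requires treatment, individual_id, n_flowers, n_fruits")
  bad <- setdiff(unique(as.character(x$treatment)), pollination_treatments())
  if (length(bad))
    fs_stop("schema_error", paste("unknown treatment level(s):", paste(bad, collapse = ", ")))
  if (any(x$n_fruits > x$n_flowers) || any(x$n_flowers < 1))
    fs_stop("integrity_error", "n_fruits must be <= n_flowers and n_flowers >= 1")
  x$treatment <- factor(as.character(x$treatment),
                        levels = intersect(pollination_treatments(),
                                           unique(as.character(x$treatment))))
  x
}

#' Write a flower table to CSV
#' @param t a `flower_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flower_table <- function(t, path) {
  write.csv(as.data.frame(t), path, row.names = FALSE)
  invisible(path)
}
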