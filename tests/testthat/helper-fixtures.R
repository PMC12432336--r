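# Shared builders for the test suite. All data are generated in code.

# tiny flower table: counts named by individual id, constant trait values
# unless `jitter` adds reproducible noise
toy_flowers <- function(counts = c(a = 2, b = 3), value = 10, jitter = 0) {
  rows <- rep(names(counts), counts)
  df <- data.frame(individual_id = rows,
                   flower_id = unlist(lapply(counts, seq_len)))
  set.seed(99)
  for (tr in floral_traits())
    df[[tr]] <- value + if (jitter > 0) rnorm(nrow(df), 0, jitter) else 0
  as_flower_table(df)
}

# vector with exact sample mean/SD: mean m, sd s
exact_ms <- function(n, m, s, seed = 1) {
  set.seed(seed)
  m + s * as.numeric(scale(rnorm(n)))
}

# pair of vectors with exact sample correlation rho
exact_cor_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  a <- as.numeric(scale(rnorm(n)))
  b <- as.numeric(scale(resid(lm(rnorm(n) ~ a))))
  cbind(x = a, y = rho * a + sqrt(1 - rho^2) * b)
}

# individual_traits table from a numeric matrix with trait columns
as_means_table <- function(X, traits = colnames(X)) {
  df <- data.frame(individual_id = sprintf("i%03d", seq_len(nrow(X))),
                   n_flowers = 1L)
  df[traits] <- as.data.frame(X)
  class(df) <- c("individual_traits", "data.frame")
  df
}

# grouped pollination table with one row per treatment
grouped_pollination <- function(p = c(spontaneous_self = 0, manual_self = 0.022,
                                      geitonogamy = 0.056, cross = 0.333,
                                      supplementation = 0.429, natural = 0.191),
                                n = c(90, 90, 90, 90, 191, 178)) {
  as_pollination_table(data.frame(
    treatment = names(p), individual_id = paste0("grp_", names(p)),
    n_flowers = n, n_fruits = round(p * n)))
}
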