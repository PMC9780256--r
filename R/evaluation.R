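#' Log-likelihood of held-out counts under a fitted model
#'
#' Recomputes each pattern's mutated/unmutated totals from the test table
#' and scores them with the training-derived pattern rates:
#' `l_M = sum(M_i log r_i + U_i log(1 - r_i))` (0 log 0 = 0). Returns
#' `-Inf` (with a warning) when a pattern has rate 0 or 1 but nonzero
#' opposing counts.
#'
#' @param model A `pattern_partition` model.
#' @param test_table A `kmer_counts` table with the same k.
#' @return Numeric scalar log-likelihood.
#' @export
log_likelihood <- function(model, test_table) {
  stopifnot(attr(test_table, "k") == model$k)
  if (nrow(test_table) == 0L ||
      sum(test_table$mutated) + sum(test_table$background) == 0) {
    return(0)
  }
  idx <- match_pattern(model, test_table$kmer)
  M <- tapply(test_table$mutated, idx, sum)
  U <- tapply(test_table$background, idx, sum)
  r <- model$patterns$rate[as.integer(names(M))]
  bad <- (r == 0 & M > 0) | (r == 1 & U > 0)
  if (any(bad)) {
    warning("pattern rate 0 or 1 with opposing counts: log-likelihood -Inf")
    return(-Inf)
  }
  t1 <- ifelse(M == 0, 0, M * log(r))
  t2 <- ifelse(U == 0, 0, U * log(1 - r))
  sum(t1 + t2)
}

#' Nagelkerke pseudo r-squared
#'
#' `r2 = (1 - exp(2 (l_0 - l_M) / n)) / (1 - exp(2 l_0 / n))`: the
#' Cox–Snell r-squared rescaled so the maximum attainable value is 1.
#' On held-out data `l_M` may fall below `l_0`, so the value can be
#' negative; it is always <= 1.
#'
#' @param l_M Model log-likelihood.
#' @param l_0 Null-model (constant-rate) log-likelihood; must be < 0.
#' @param n Number of sites (total mutated + unmutated count).
#' @return Numeric scalar.
#' @export
nagelkerke_r2 <- function(l_M, l_0, n) {
  stopifnot(n > 0)
  if (l_0 == 0) stop("null log-likelihood of 0: r2 undefined", call. = FALSE)
  stopifnot(l_0 < 0)
  (1 - exp(2 * (l_0 - l_M) / n)) / (1 - exp(2 * l_0 / n))
}

null_log_likelihood <- function(M, U, rate) {
  t1 <- if (M == 0) 0 else M * log(rate)
  t2 <- if (U == 0) 0 else U * log(1 - rate)
  t1 + t2
}

#' Evaluate fitted models on held-out count tables
#'
#' Computes, per mutation class and jointly, the model log-likelihood, the
#' null (constant-rate) log-likelihood, the number of sites and the
#' Nagelkerke pseudo r-squared. The joint row pools l_M, l_0 and n across
#' classes before applying the r-squared formula.
#'
#' @param models Named list of `pattern_partition` models.
#' @param test_tables Named list of `kmer_counts` tables (same names).
#' @param null_rate `"test"` (default): the null model uses each test
#'   table's own mean rate, so r2 = 0 means "no better than a constant fitted
#'   to the test data"; `"train"` uses the training mean rate instead.
#' @return A tibble with columns `mut_class`, `l_M`, `l_0`, `n`, `r2`; the
#'   final row (`mut_class = "joint"`) pools across classes.
#' @export
evaluate_models <- function(models, test_tables,
                            null_rate = c("test", "train")) {
  null_rate <- match.arg(null_rate)
  stopifnot(all(names(models) %in% names(test_tables)))
  rows <- lapply(names(models), function(cl) {
    tt <- test_tables[[cl]]
    M <- sum(tt$mutated)
    U <- sum(tt$background)
    mu0 <- if (null_rate == "test") mean_rate(tt) else models[[cl]]$mu
    tibble::tibble(
      mut_class = cl,
      l_M = log_likelihood(models[[cl]], tt),
      l_0 = null_log_likelihood(M, U, mu0),
      n = M + U)
  })
  df <- dplyr::bind_rows(rows)
  joint <- tibble::tibble(mut_class = "joint", l_M = sum(df$l_M),
                          l_0 = sum(df$l_0), n = sum(df$n))
  df <- dplyr::bind_rows(df, joint)
  df$r2 <- mapply(nagelkerke_r2, df$l_M, df$l_0, df$n)
  df
}
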