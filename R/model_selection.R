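#' Split a k-mer count table into two folds
#'
#' Mutated counts are divided by multivariate hypergeometric sampling:
#' fold 1 receives exactly `floor(sum(m)/2)` mutations drawn without
#' replacement across k-mers, fold 2 the remainder; background counts are
#' split the same way, independently. The folds always add back up to the
#' original table.
#'
#' @param table A `kmer_counts` table with total counts >= 2.
#' @param seed Integer seed.
#' @return A list of two `kmer_counts` tables.
#' @export
split_table <- function(table, seed = 1L) {
  stopifnot(sum(table$mutated) + sum(table$background) >= 2)
  with_seed(seed, {
    m1 <- rmvhyper(table$mutated, floor(sum(table$mutated) / 2))
    u1 <- rmvhyper(table$background, floor(sum(table$background) / 2))
  })
  k <- attr(table, "k")
  cl <- attr(table, "mut_class")
  list(
    new_kmer_counts(table$kmer, m1, u1, k, cl),
    new_kmer_counts(table$kmer, table$mutated - m1,
                    table$background - u1, k, cl)
  )
}

# multivariate hypergeometric draw: ndraw balls without replacement from
# categories with the given counts
rmvhyper <- function(counts, ndraw) {
  out <- numeric(length(counts))
  rest <- sum(counts)
  for (j in seq_along(counts)) {
    rest <- rest - counts[j]
    x <- stats::rhyper(1L, counts[j], rest, ndraw)
    out[j] <- x
    ndraw <- ndraw - x
  }
  out
}

#' Cross-validation configuration
#'
#' @param alpha_grid,c_grid Candidate pseudo counts and complexity
#'   penalties.
#' @param n_repeats Number of independent 2-fold splits (default 5).
#' @param seed Master seed; all splits derive from it.
#' @return A `cv_config` list.
#' @export
cv_config <- function(alpha_grid = c(0.1, 0.5, 1, 2, 5, 10, 20),
                      c_grid = c(0.5, 1, 2, 5, 10, 20, 50, 100),
                      n_repeats = 5L, seed = 1L) {
  stopifnot(length(alpha_grid) > 0, length(c_grid) > 0, n_repeats >= 1)
  structure(list(alpha_grid = alpha_grid, c_grid = c_grid,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_config")
}

# negative log-likelihood of held-out counts under a trained model
heldout_nll <- function(model, test_table) {
  -log_likelihood(model, test_table)
}

#' Hyperparameter selection by repeated two-fold cross-validation
#'
#' For every (alpha, c) grid point and every repeat, the count table is
#' split in two by hypergeometric sampling; a partition is trained on each
#' fold and scored by the negative log-likelihood of the opposite fold
#' under the trained pattern rates. The pair minimizing the mean over all
#' `2 * n_repeats` evaluations is selected; ties prefer the larger c, then
#' the larger alpha. Splits depend only on the config seed, so results are
#' identical regardless of the order grid points are evaluated in.
#'
#' @param table A `kmer_counts` table.
#' @param config A [cv_config()].
#' @param optimizer `"exact"` or `"greedy"`.
#' @return A `cv_result`: list with `grid` (mean NLL per pair), `details`
#'   (per repeat and fold), and `selected` (named list `alpha`, `c_penalty`).
#' @export
grid_search <- function(table, config = cv_config(),
                        optimizer = c("exact", "greedy")) {
  optimizer <- match.arg(optimizer)
  fit <- if (optimizer == "exact") optimal_partition else greedy_partition
  splits <- lapply(seq_len(config$n_repeats), function(rep) {
    split_table(table, seed = mix_seed(config$seed, "cv-split", rep))
  })
  grid <- tidyr::expand_grid(alpha = config$alpha_grid,
                             c_penalty = config$c_grid)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    a <- grid$alpha[g]
    cc <- grid$c_penalty[g]
    for (rep in seq_len(config$n_repeats)) {
      for (fold in 1:2) {
        train <- splits[[rep]][[fold]]
        test <- splits[[rep]][[3L - fold]]
        nll <- tryCatch({
          m <- fit(train, alpha = a, c_penalty = cc)
          heldout_nll(m, test)
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          alpha = a, c_penalty = cc, rep = rep, fold = fold,
          test_nll = nll)
      }
    }
  }
  details <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(details, .data$alpha, .data$c_penalty),
    mean_nll = mean(.data$test_nll),
    n_valid = sum(is.finite(.data$test_nll)), .groups = "drop")
  invalid <- !is.finite(summary$mean_nll)
  if (any(invalid)) {
    warning(sum(invalid), " grid point(s) invalid (degenerate fold fit),",
            " excluded from selection")
  }
  cand <- summary[!invalid, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no valid grid point", call. = FALSE)
  cand <- cand[order(cand$mean_nll, -cand$c_penalty, -cand$alpha), ]
  structure(list(grid = summary, details = details,
                 selected = list(alpha = cand$alpha[1L],
                                 c_penalty = cand$c_penalty[1L])),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation over", nrow(x$grid), "grid points\n")
  cat("selected: alpha =", x$selected$alpha,
      " c =", x$selected$c_penalty, "\n")
  print(dplyr::arrange(x$grid, .data$mean_nll), n = 5)
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-(alpha, c) mean out-of-sample NLL tibble.
#' @export
tidy.cv_result <- function(x, ...) x$grid

#' Plot the cross-validation surface
#'
#' Mean out-of-sample negative log-likelihood over the (alpha, c) grid,
#' with the selected pair highlighted.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$grid
  sel <- tibble::tibble(alpha = object$selected$alpha,
                        c_penalty = object$selected$c_penalty)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$alpha),
                                   y = factor(.data$c_penalty),
                                   fill = .data$mean_nll)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = sel, ggplot2::aes(fill = NULL),
                        shape = 21, size = 3, fill = "white") +
    ggplot2::labs(x = "pseudo count (alpha)", y = "complexity penalty (c)",
                  fill = "mean test NLL",
                  title = "Cross-validation surface") +
    ggplot2::theme_minimal()
}

#' Train a model with CV-selected hyperparameters
#'
#' Runs [grid_search()] and refits on the full table at the selected
#' (alpha, c).
#'
#' @inheritParams grid_search
#' @return A `pattern_partition` model with a `cv` attribute holding the
#'   `cv_result`.
#' @export
train_model <- function(table, config = cv_config(),
                        optimizer = c("exact", "greedy")) {
  optimizer <- match.arg(optimizer)
  cv <- grid_search(table, config, optimizer)
  fit <- if (optimizer == "exact") optimal_partition else greedy_partition
  model <- fit(table, alpha = cv$selected$alpha,
               c_penalty = cv$selected$c_penalty)
  attr(model, "cv") <- cv
  model
}
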