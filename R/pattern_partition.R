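#' Regularized per-pattern mutation rate
#'
#' The rate estimate for sites matching a pattern, shrunk toward the table's
#' mean rate `mu` by a pseudo count `alpha`:
#' `r = (M + alpha) / (M + U + alpha / mu)`.
#' With `alpha = 0` this is the raw MLE `M / (M + U)`; an empty pattern
#' (`M = U = 0`) gets exactly `mu`.
#'
#' @param M,U Mutated and unmutated counts (vectorized).
#' @param mu Mean mutation rate of the table.
#' @param alpha Pseudo count, >= 0.
#' @return Numeric vector of rates.
#' @export
regularized_rate <- function(M, U, mu, alpha) {
  r <- (M + alpha) / (M + U + alpha / mu)
  empty <- (M + U + alpha) == 0
  r[empty] <- mu
  r
}

#' Per-pattern contribution to the partition loss
#'
#' The penalized binomial deviance of one pattern:
#' `-2 (M log r + U log(1 - r)) + c`, with the regularized rate `r` and the
#' convention `0 * log 0 = 0`. At `c = 2` the total loss of a partition is
#' the AIC of the corresponding binomial model (one rate parameter per
#' pattern); natural logarithms are used so that identity holds in its
#' conventional form.
#'
#' @inheritParams regularized_rate
#' @param c_penalty Complexity penalty added per pattern.
#' @return Numeric vector of loss contributions (deviance units).
#' @export
pattern_loss <- function(M, U, mu, alpha = 0, c_penalty = 0) {
  r <- regularized_rate(M, U, mu, alpha)
  t1 <- ifelse(M == 0, 0, M * log(r))
  t2 <- ifelse(U == 0, 0, U * log(1 - r))
  -2 * (t1 + t2) + c_penalty
}

# ---- internal machinery shared by the exact DP and the greedy search ----

CODE_SETS <- list(
  "A", "C", "G", "T",
  c("C", "G"), c("A", "T"), c("A", "G"), c("C", "T"), c("G", "T"),
  c("A", "C"),
  c("C", "G", "T"), c("A", "G", "T"), c("A", "C", "T"), c("A", "C", "G"),
  c("A", "C", "G", "T")
)
CODE_SIZE <- lengths(CODE_SETS)

# two-partitions as code indices, in Table order
code_pairs <- function() {
  lapply(IUPAC_CODES, function(cd) {
    prs <- if (cd %in% names(IUPAC_TWO_PARTITIONS)) {
      IUPAC_TWO_PARTITIONS[[cd]]
    } else list()
    if (length(prs) == 0L) {
      matrix(integer(0), ncol = 2L)
    } else {
      t(vapply(prs, function(xy) match(xy, IUPAC_CODES), integer(2L)))
    }
  })
}

# counts tibble -> numeric vector of length 4^k (axis i = position i,
# base order A,C,G,T, stride 4^(i-1))
counts_to_array <- function(kmers, counts, k) {
  m <- matrix(match(unlist(strsplit(kmers, "")), c("A", "C", "G", "T")),
              ncol = k, byrow = TRUE)
  idx <- 1L + as.integer((m - 1L) %*% 4L^(0:(k - 1L)))
  out <- numeric(4L^k)
  out[idx] <- counts
  out
}

# aggregate a 4^k count vector into sums over every IUPAC pattern: returns a
# vector of length 15^k where entry for pattern p is the sum over matching
# k-mers (one axis transform 4 -> 15 per position)
pattern_sums <- function(arr, k) {
  Z <- matrix(0, 15L, 4L)
  for (ci in seq_len(15L)) {
    Z[ci, match(CODE_SETS[[ci]], c("A", "C", "G", "T"))] <- 1
  }
  dims <- rep(4L, k)
  for (i in seq_len(k)) {
    a <- array(arr, dims)
    perm <- c(i, setdiff(seq_len(k), i))
    a <- aperm(a, perm)
    m2 <- Z %*% matrix(a, nrow = dims[i])
    dims[i] <- 15L
    a2 <- array(m2, c(15L, dims[perm[-1L]]))
    arr <- as.vector(aperm(a2, order(perm)))
  }
  arr
}

pattern_index_digits <- function(P, k) {
  d <- matrix(0L, P, k)
  ix <- 0:(P - 1L)
  for (i in seq_len(k)) {
    d[, i] <- (ix %/% 15L^(i - 1L)) %% 15L + 1L
  }
  d
}

digits_to_pattern <- function(d) {
  paste0(IUPAC_CODES[d], collapse = "")
}

model_hyperparams <- function(alpha, c_penalty) {
  stopifnot(is.finite(alpha), alpha >= 0, is.finite(c_penalty),
            c_penalty >= 0)
  list(alpha = alpha, c_penalty = c_penalty)
}

central_restriction <- function(table) {
  # SNV tables are keyed by collapsed k-mers (central A or C); the central
  # pattern position then only ranges over codes A, C, M
  if (attr(table, "mut_class") %in% SNV_CLASSES) {
    (attr(table, "k") + 1L) %/% 2L
  } else {
    0L
  }
}

new_pattern_model <- function(patterns, k, mut_class, alpha, c_penalty, mu,
                              loss, method) {
  structure(
    list(patterns = patterns, k = as.integer(k), mut_class = mut_class,
         alpha = alpha, c_penalty = c_penalty, mu = mu, loss = loss,
         method = method),
    class = "pattern_partition"
  )
}

#' @export
print.pattern_partition <- function(x, ...) {
  cat("Pattern partition model (", x$mut_class, ", k=", x$k, ", ",
      x$method, ")\n", sep = "")
  cat("  patterns: ", nrow(x$patterns), "  loss: ", format(x$loss),
      "  mu: ", format(x$mu), "\n", sep = "")
  cat("  alpha: ", x$alpha, "  c: ", x$c_penalty, "\n", sep = "")
  print(x$patterns, n = 10)
  invisible(x)
}

#' Optimal pattern partition by exact dynamic programming
#'
#' Finds, over all pattern partitions reachable by recursively two-partition
#' splitting the all-N pattern (central position restricted to A/C/M for
#' strand-collapsed SNV tables), the one minimizing the penalized binomial
#' deviance. The recursion
#' `f(p) = min(loss({p}), min over splits f(p_x) + f(p_y))`
#' is evaluated bottom-up over all `15^k` patterns, ordered by coarseness,
#' so each pattern is solved once. Ties prefer not splitting, then the first
#' split in the fixed two-partition order.
#'
#' @param table A `kmer_counts` table.
#' @param alpha Pseudo count.
#' @param c_penalty Complexity penalty per pattern.
#' @param max_patterns Refuse (suggesting [greedy_partition()]) when `15^k`
#'   exceeds this guard.
#' @return A `pattern_partition` model: a list with the `patterns` tibble
#'   (`pattern`, `mutated`, `background`, `rate`), hyperparameters, `mu` and
#'   the total `loss`.
#' @export
optimal_partition <- function(table, alpha = 1, c_penalty = 2,
                              max_patterns = 2e6) {
  hp <- model_hyperparams(alpha, c_penalty)
  k <- attr(table, "k")
  if (15^k > max_patterns) {
    stop("pattern space 15^", k, " exceeds max_patterns guard (",
         max_patterns, "); use greedy_partition() for large k",
         call. = FALSE)
  }
  mu <- mean_rate(table)
  if (!is.finite(mu) || mu <= 0 || mu >= 1) {
    stop("degenerate table: mean rate must lie strictly in (0, 1)",
         call. = FALSE)
  }
  P <- 15L^k
  Marr <- pattern_sums(counts_to_array(table$kmer, table$mutated, k), k)
  Uarr <- pattern_sums(counts_to_array(table$kmer, table$background, k), k)
  f <- pattern_loss(Marr, Uarr, mu, hp$alpha, hp$c_penalty)
  digits <- pattern_index_digits(P, k)
  coarse <- matrix(CODE_SIZE[digits], P, k)
  coarse <- apply(coarse, 1L, prod)
  cpos <- central_restriction(table)
  valid <- rep(TRUE, P)
  if (cpos > 0L) {
    valid <- digits[, cpos] %in% c(1L, 2L, 10L)  # A, C, M
  }
  pairs <- code_pairs()
  strides <- 15L^(0:(k - 1L))
  split_pos <- integer(P)
  split_pair <- integer(P)
  ord <- which(valid & coarse > 1L)
  ord <- ord[order(coarse[ord])]
  for (idx in ord) {
    best <- f[idx]
    bpos <- 0L
    bpair <- 0L
    for (i in seq_len(k)) {
      prs <- pairs[[digits[idx, i]]]
      if (nrow(prs) == 0L) next
      st <- strides[i]
      d0 <- digits[idx, i]
      for (j in seq_len(nrow(prs))) {
        tot <- f[idx + (prs[j, 1L] - d0) * st] +
               f[idx + (prs[j, 2L] - d0) * st]
        if (tot < best) {
          best <- tot
          bpos <- i
          bpair <- j
        }
      }
    }
    if (bpos > 0L) {
      f[idx] <- best
      split_pos[idx] <- bpos
      split_pair[idx] <- bpair
    }
  }
  root_digits <- rep(15L, k)
  if (cpos > 0L) root_digits[cpos] <- 10L
  root <- 1L + sum((root_digits - 1L) * strides)
  # reconstruct the optimal partition's leaves
  leaves <- integer(0)
  stack <- root
  while (length(stack)) {
    idx <- stack[1L]
    stack <- stack[-1L]
    if (split_pos[idx] == 0L) {
      leaves <- c(leaves, idx)
    } else {
      i <- split_pos[idx]
      pr <- pairs[[digits[idx, i]]][split_pair[idx], ]
      st <- strides[i]
      d0 <- digits[idx, i]
      stack <- c(idx + (pr[1L] - d0) * st, idx + (pr[2L] - d0) * st, stack)
    }
  }
  pats <- vapply(leaves, function(ix) digits_to_pattern(digits[ix, ]), "")
  M <- Marr[leaves]
  U <- Uarr[leaves]
  model <- new_pattern_model(
    tibble::tibble(pattern = pats, mutated = M, background = U,
                   rate = regularized_rate(M, U, mu, hp$alpha)),
    k, attr(table, "mut_class"), hp$alpha, hp$c_penalty, mu,
    loss = f[root], method = "exact")
  model
}

#' Greedy pattern partition
#'
#' A fast heuristic: starting from the all-N pattern, repeatedly apply the
#' single most promising two-partition split (the one minimizing the summed
#' single-pattern losses of the two children), recursing into each child;
#' a pattern is kept as a leaf when no split improves on its own loss.
#' Always returns a valid partition; its loss is never below the exact
#' optimum but the search is polynomial, so much larger k are feasible.
#'
#' @inheritParams optimal_partition
#' @return A `pattern_partition` model.
#' @export
greedy_partition <- function(table, alpha = 1, c_penalty = 2) {
  hp <- model_hyperparams(alpha, c_penalty)
  k <- attr(table, "k")
  mu <- mean_rate(table)
  if (!is.finite(mu) || mu <= 0 || mu >= 1) {
    stop("degenerate table: mean rate must lie strictly in (0, 1)",
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  marr <- array(counts_to_array(table$kmer, table$mutated, k), rep(4L, k))
  uarr <- array(counts_to_array(table$kmer, table$background, k), rep(4L, k))
  cpos <- central_restriction(table)
  root_codes <- rep(15L, k)
  if (cpos > 0L) root_codes[cpos] <- 10L
  pairs <- code_pairs()

  slice <- function(arr, axis, keep) {
    idx <- rep(list(quote(expr = )), k)
    idx[[axis]] <- keep
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  leaves <- list()
  recurse <- function(codes, m, u) {
    M <- sum(m)
    U <- sum(u)
    self_loss <- pattern_loss(M, U, mu, hp$alpha, hp$c_penalty)
    best <- self_loss
    bsplit <- NULL
    for (i in seq_len(k)) {
      prs <- pairs[[codes[i]]]
      if (nrow(prs) == 0L) next
      mm <- apply(m, i, sum)
      uu <- apply(u, i, sum)
      axis_bases <- CODE_SETS[[codes[i]]]
      for (j in seq_len(nrow(prs))) {
        ix <- match(CODE_SETS[[prs[j, 1L]]], axis_bases)
        iy <- match(CODE_SETS[[prs[j, 2L]]], axis_bases)
        tot <- pattern_loss(sum(mm[ix]), sum(uu[ix]), mu, hp$alpha,
                            hp$c_penalty) +
               pattern_loss(sum(mm[iy]), sum(uu[iy]), mu, hp$alpha,
                            hp$c_penalty)
        if (tot < best) {
          best <- tot
          bsplit <- list(i = i, x = prs[j, 1L], y = prs[j, 2L],
                         ix = ix, iy = iy)
        }
      }
    }
    if (is.null(bsplit)) {
      leaves[[length(leaves) + 1L]] <<- list(
        pattern = digits_to_pattern(codes), M = M, U = U)
    } else {
      cx <- codes; cx[bsplit$i] <- bsplit$x
      cy <- codes; cy[bsplit$i] <- bsplit$y
      recurse(cx, slice(m, bsplit$i, bsplit$ix), slice(u, bsplit$i, bsplit$ix))
      recurse(cy, slice(m, bsplit$i, bsplit$iy), slice(u, bsplit$i, bsplit$iy))
    }
  }
  recurse(root_codes, marr, uarr)
  M <- vapply(leaves, `[[`, 0, "M")
  U <- vapply(leaves, `[[`, 0, "U")
  pats <- vapply(leaves, `[[`, "", "pattern")
  loss <- sum(pattern_loss(M, U, mu, hp$alpha, hp$c_penalty))
  new_pattern_model(
    tibble::tibble(pattern = pats, mutated = M, background = U,
                   rate = regularized_rate(M, U, mu, hp$alpha)),
    k, attr(table, "mut_class"), hp$alpha, hp$c_penalty, mu, loss,
    method = "greedy")
}

#' Map k-mers to the pattern of a model that matches them
#'
#' Every k-mer is matched by exactly one pattern of a valid partition.
#'
#' @param model A `pattern_partition` model.
#' @param kmers Character vector of k-mers.
#' @return Integer vector of row indices into `model$patterns`.
#' @export
match_pattern <- function(model, kmers) {
  lookup <- pattern_kmer_lookup(model)
  out <- lookup[kmers]
  if (anyNA(out)) {
    stop("k-mer(s) not matched by any model pattern: ",
         paste(utils::head(kmers[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

.lookup_cache <- new.env(parent = emptyenv())

pattern_kmer_lookup <- function(model) {
  key <- paste(model$k, paste(model$patterns$pattern, collapse = ","))
  hit <- .lookup_cache[[key]]
  if (!is.null(hit)) return(hit)
  exp_list <- lapply(model$patterns$pattern, expand_pattern)
  idx <- rep(seq_along(exp_list), lengths(exp_list))
  out <- stats::setNames(idx, unlist(exp_list))
  .lookup_cache[[key]] <- out
  out
}

#' Per-k-mer rates implied by a model
#'
#' @param model A `pattern_partition` model.
#' @param kmers k-mers to score (defaults to all the model covers).
#' @return A tibble with columns `kmer`, `pattern`, `rate`.
#' @export
kmer_rates <- function(model, kmers = NULL) {
  lookup <- pattern_kmer_lookup(model)
  if (is.null(kmers)) kmers <- names(lookup)
  idx <- unname(lookup[kmers])
  tibble::tibble(kmer = kmers,
                 pattern = model$patterns$pattern[idx],
                 rate = model$patterns$rate[idx])
}

#' Write a pattern model to TSV
#'
#' The file carries metadata comment lines (#k, #mut_class, #alpha, #c, #mu,
#' #loss) followed by a header and one row per pattern. The same format is
#' the input of the gene-level expectation engine.
#'
#' @param model A `pattern_partition` model.
#' @param path Output path.
#' @return The model, invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#k=", model$k),
    paste0("#mut_class=", model$mut_class),
    paste0("#alpha=", format(model$alpha, digits = 17)),
    paste0("#c=", format(model$c_penalty, digits = 17)),
    paste0("#mu=", format(model$mu, digits = 17)),
    paste0("#loss=", format(model$loss, digits = 17)),
    paste("pattern", "mutated_count", "background_count", "rate",
          sep = "\t")), con)
  writeLines(paste(model$patterns$pattern,
                   format(model$patterns$mutated, digits = 17),
                   format(model$patterns$background, digits = 17),
                   format(model$patterns$rate, digits = 17),
                   sep = "\t"), con)
  invisible(model)
}

#' Read a pattern model from TSV
#'
#' @param path A file written by [write_model()].
#' @return A `pattern_partition` model.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^#", "", meta_lines), "=")
  vals <- stats::setNames(vapply(meta, `[[`, "", 2L),
                          vapply(meta, `[[`, "", 1L))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  new_pattern_model(
    tibble::tibble(pattern = df$pattern, mutated = df$mutated_count,
                   background = df$background_count, rate = df$rate),
    k = as.integer(vals[["k"]]), mut_class = vals[["mut_class"]],
    alpha = as.numeric(vals[["alpha"]]),
    c_penalty = as.numeric(vals[["c"]]),
    mu = as.numeric(vals[["mu"]]), loss = as.numeric(vals[["loss"]]),
    method = "file")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pattern partition model
#'
#' @param x A `pattern_partition` model.
#' @param ... Unused.
#' @return The `patterns` tibble with a `rel_rate` column (rate relative to
#'   the table mean).
#' @export
tidy.pattern_partition <- function(x, ...) {
  dplyr::mutate(x$patterns, rel_rate = .data$rate / x$mu)
}

#' One-row summary of a pattern partition model
#'
#' @param x A `pattern_partition` model.
#' @param ... Unused.
#' @return A one-row tibble: class, k, number of patterns, hyperparameters,
#'   mean rate and total loss.
#' @export
glance.pattern_partition <- function(x, ...) {
  tibble::tibble(mut_class = x$mut_class, k = x$k,
                 n_patterns = nrow(x$patterns), alpha = x$alpha,
                 c_penalty = x$c_penalty, mu = x$mu, loss = x$loss,
                 method = x$method)
}

#' Plot the relative rate of each pattern in a model
#'
#' Patterns ordered by rate, point size reflecting the number of matching
#' genomic opportunities, rate axis log-scaled relative to the mean.
#'
#' @param object A `pattern_partition` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_partition <- function(object, ...) {
  df <- tidy(object)
  df$pattern <- factor(df$pattern, levels = df$pattern[order(df$rel_rate)])
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rel_rate, y = .data$pattern,
    size = .data$mutated + .data$background)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate relative to mean", y = NULL,
                  size = "opportunities",
                  title = paste0(object$mut_class, " pattern rates (k=",
                                 object$k, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
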