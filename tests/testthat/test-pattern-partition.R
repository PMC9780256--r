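test_that("regularized rate and loss handle degenerate inputs by convention", {
  # empty pattern: both log terms vanish, loss is the bare penalty
  expect_equal(pattern_loss(0, 0, mu = 0.01, alpha = 2, c_penalty = 7), 7)
  # alpha = 0 reduces to the raw MLE
  expect_equal(regularized_rate(3, 1, mu = 0.5, alpha = 0), 3 / 4)
  # empty pattern rate collapses to mu for any alpha
  expect_equal(regularized_rate(0, 0, mu = 0.013, alpha = 1), 0.013)
  expect_equal(regularized_rate(0, 0, mu = 0.013, alpha = 0), 0.013)
  # regularization pulls toward mu
  r0 <- regularized_rate(10, 90, mu = 0.01, alpha = 0)
  r1 <- regularized_rate(10, 90, mu = 0.01, alpha = 50)
  expect_true(abs(r1 - 0.01) < abs(r0 - 0.01))
})

test_that("loss at c = 2 equals AIC from an independent binomial routine", {
  tab <- rand_snv_table(101)
  mu <- mean_rate(tab)
  km <- tab$kmer
  for (pats in list("NCN", c("NCG", "NCH"), c("SCS", "SCW", "WCS", "WCW"))) {
    M <- vapply(pats, function(p) sum(tab$mutated[pattern_matches(p, km)]), 0)
    U <- vapply(pats, function(p) sum(tab$background[pattern_matches(p, km)]), 0)
    loss <- sum(pattern_loss(M, U, mu, alpha = 0, c_penalty = 2))
    r <- M / (M + U)
    # independent log-likelihood via dbinom minus the binomial coefficient
    ll <- sum(stats::dbinom(M, M + U, r, log = TRUE) - lchoose(M + U, M))
    aic <- 2 * length(pats) - 2 * ll
    expect_equal(loss, aic, tolerance = 1e-10)
  }
})

test_that("exact DP equals the exhaustive recursion oracle for k <= 3", {
  for (seed in 1:4) {
    tab <- rand_indel_table(seed, k = 2)
    d <- optimal_partition(tab, alpha = 1, c_penalty = 2)
    o <- oracle_partition_loss(tab, 1, 2, root = "NN", memo = FALSE)
    expect_equal(d$loss, o)
  }
  for (seed in 5:8) {
    tab <- rand_snv_table(seed)
    d <- optimal_partition(tab, alpha = 0.5, c_penalty = 3)
    o <- oracle_partition_loss(tab, 0.5, 3, root = "NMN")
    expect_equal(d$loss, o)
  }
})

test_that("every returned model is a valid partition with conserved counts", {
  for (seed in c(11, 12)) {
    tab <- rand_snv_table(seed)
    for (fit in list(optimal_partition(tab, 1, 2),
                     greedy_partition(tab, 1, 2))) {
      space <- all_kmers(3, central = "C")
      nmatch <- rowSums(vapply(fit$patterns$pattern,
                               function(p) pattern_matches(p, space),
                               logical(length(space))))
      expect_true(all(nmatch == 1))
      expect_equal(sum(fit$patterns$mutated), sum(tab$mutated))
      expect_equal(sum(fit$patterns$background), sum(tab$background))
      expect_equal(fit$loss,
                   sum(pattern_loss(fit$patterns$mutated,
                                    fit$patterns$background, fit$mu,
                                    fit$alpha, fit$c_penalty)))
    }
  }
})

test_that("homogeneous tables yield the single root pattern", {
  km <- all_kmers(3, central = "C")
  tab <- kmer_counts(km, rep(5, 16), rep(200, 16), mut_class = "C>T")
  for (fit in list(optimal_partition(tab, 1, 10),
                   greedy_partition(tab, 1, 10))) {
    expect_equal(nrow(fit$patterns), 1)
  }
})

test_that("greedy fully splits when splitting is free and rates differ", {
  km <- all_kmers(1)
  tab <- kmer_counts(km, c(1, 2, 4, 8), c(100, 100, 100, 100),
                     mut_class = "DEL")
  g <- greedy_partition(tab, alpha = 1e-9, c_penalty = 0)
  expect_equal(sort(g$patterns$pattern), c("A", "C", "G", "T"))
})

test_that("DP is deterministic and monotone in the complexity penalty", {
  tab <- rand_snv_table(31)
  f1 <- optimal_partition(tab, 1, 2)
  f2 <- optimal_partition(tab, 1, 2)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$patterns, f2$patterns)
  sizes <- vapply(c(0.5, 1, 2, 5, 10, 50, 200),
                  function(cc) nrow(optimal_partition(tab, 1, cc)$patterns),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("degenerate tables and oversized k are refused", {
  km <- all_kmers(1)
  empty_m <- kmer_counts(km, rep(0, 4), rep(10, 4), mut_class = "DEL")
  expect_error(optimal_partition(empty_m, 1, 2), "degenerate")
  expect_error(greedy_partition(empty_m, 1, 2), "degenerate")
  big <- kmer_counts(all_kmers(3), rep(1, 64), rep(10, 64),
                     mut_class = "DEL")
  expect_error(optimal_partition(big, 1, 2, max_patterns = 100),
               "greedy_partition")
})

test_that("model files round-trip", {
  tab <- rand_snv_table(77)
  m <- optimal_partition(tab, 0.5, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$patterns$pattern, m$patterns$pattern)
  expect_equal(back$patterns$rate, m$patterns$rate)
  expect_equal(back$k, m$k)
  expect_equal(back$mu, m$mu)
  expect_equal(back$loss, m$loss)
  expect_equal(back$mut_class, m$mut_class)
})

test_that("tidy, glance and autoplot expose the fitted model", {
  m <- optimal_partition(rand_snv_table(55), 1, 2)
  td <- tidy(m)
  expect_true(all(c("pattern", "rate", "rel_rate") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_patterns, nrow(m$patterns))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("k-mer to pattern lookup covers the space exactly once", {
  m <- optimal_partition(rand_snv_table(90), 1, 2)
  kr <- kmer_rates(m, all_kmers(3, central = "C"))
  expect_equal(nrow(kr), 16)
  expect_false(anyNA(kr$rate))
  expect_error(match_pattern(m, "GGG"), "not matched")
})
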