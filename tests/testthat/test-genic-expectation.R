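test_that("SNV classification matches a translate-and-compare oracle", {
  fx <- genic_fixture()
  gc <- Biostrings::GENETIC_CODE
  for (tx in fx$transcripts[1:2]) {
    s <- as.character(fx$genome[[tx$chrom]])
    cs <- cds_seq(tx, fx$genome)
    cpos <- mutpatterns:::cds_positions(tx)
    n_codons <- nchar(cs) / 3
    idx <- c(1:6, sample(seq_along(cpos), 40),
             (length(cpos) - 5):length(cpos))
    for (i in unique(idx)) {
      p1 <- cpos[i] + 1
      ref <- substr(s, p1, p1)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- classify_snv(tx, fx$genome, p1, ref, alt)
        alt_c <- if (tx$strand == "-") mutpatterns:::COMPLEMENT[[alt]] else alt
        cs2 <- cs
        substr(cs2, i, i) <- alt_c
        ci <- (i - 1) %/% 3 + 1
        old_aa <- gc[[substr(cs, 3 * ci - 2, 3 * ci)]]
        new_aa <- gc[[substr(cs2, 3 * ci - 2, 3 * ci)]]
        want <- if (ci == 1) "start_disruption"
          else if (ci == n_codons) {
            if (new_aa == "*") "synonymous" else "stop_disruption"
          } else if (new_aa == "*") "nonsense"
          else if (new_aa == old_aa) "synonymous"
          else "missense"
        expect_equal(got, want)
      }
    }
    # intronic flank bases are splice disruptions
    for (sp in tx$splice_sites) {
      ref <- substr(s, sp + 1, sp + 1)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      expect_equal(classify_snv(tx, fx$genome, sp + 1, ref, alt),
                   "splice_disruption")
    }
    expect_error(classify_snv(tx, fx$genome, 1, substr(s, 1, 1), "N"),
                 "outside")
  }
})

test_that("hand-coded codon cases classify correctly", {
  # single-exon +strand transcript: ATG GCT TGG TAA
  gen <- as_genome(c(c1 = paste0("AAAA", "ATGGCTTGGTAA", "AAAA")))
  tx <- transcript_model("t", "c1", "+",
                         tibble::tibble(start = 4, end = 16), gen)
  expect_true(tx$canonical)
  # GCT -> GCC is Ala->Ala
  expect_equal(classify_snv(tx, gen, 10, "T", "C"), "synonymous")
  # TGG -> TGA is stop gain
  expect_equal(classify_snv(tx, gen, 13, "G", "A"), "nonsense")
  # start codon
  expect_equal(classify_snv(tx, gen, 5, "A", "G"), "start_disruption")
  # stop codon TAA -> TAG stays stop
  expect_equal(classify_snv(tx, gen, 16, "A", "G"), "synonymous")
  # stop codon TAA -> CAA is lost
  expect_equal(classify_snv(tx, gen, 14, "T", "C"), "stop_disruption")
})

test_that("site tables enumerate 3 entries per position and sum by category", {
  fx <- genic_fixture()
  tx <- fx$transcripts[[1]]
  st <- transcript_site_table(tx, fx$genome, fx$snv_models, n_gen = 100)
  n_pos <- length(mutpatterns:::cds_positions(tx)) + length(tx$splice_sites)
  expect_equal(nrow(st), 3 * n_pos)
  expect_true(all(st$r_scaled >= 0 & st$r_scaled < 1))
  expect_equal(st$r_scaled, 1 - (1 - st$rate)^(2 * 100))
  ec <- expected_counts(tx, fx$genome, fx$snv_models, fx$indel_models,
                        n_gen = 100)
  snv_cats <- setdiff(ec$expectations$category,
                      c("inframe_indel", "frameshift_indel"))
  for (cat in snv_cats) {
    expect_equal(ec$expectations$expected[ec$expectations$category == cat],
                 sum(st$r_scaled[st$category == cat]))
  }
  # additivity across categories
  expect_equal(sum(ec$expectations$expected[
    ec$expectations$category %in% snv_cats]), sum(st$r_scaled))
  # n_gen = 0 zeroes everything
  ec0 <- expected_counts(tx, fx$genome, fx$snv_models, fx$indel_models, 0)
  expect_true(all(ec0$expectations$expected == 0))
})

test_that("uniform rates make category expectations proportional to counts", {
  gen <- as_genome(c(c1 = paste0(
    "AAAA", "ATGGCTAGGTCACTGTGTCCACTTTGGTAA", "AAAA")))
  tx <- transcript_model("t", "c1", "+",
                         tibble::tibble(start = 4, end = 34), gen)
  flat <- function(cl) {
    structure(list(
      patterns = tibble::tibble(pattern = "NMN", mutated = 0,
                                background = 0, rate = 1e-4),
      k = 3L, mut_class = cl, alpha = 0, c_penalty = 0, mu = 1e-4,
      loss = NA_real_, method = "flat"), class = "pattern_partition")
  }
  models <- stats::setNames(
    lapply(c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T"), flat),
    c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T"))
  st <- transcript_site_table(tx, gen, models, n_gen = 1)
  tab <- table(st$category)
  ec <- expected_counts(tx, gen, models, n_gen = 1)
  for (cat in names(tab)) {
    expect_equal(
      ec$expectations$expected[ec$expectations$category == cat] /
        sum(ec$expectations$expected),
      unname(tab[cat]) / sum(tab))
  }
})

test_that("rate rescaling hits the target means exactly", {
  fx <- genic_fixture()
  snv_mean <- genome_mean_snv_rate(fx$snv_models, fx$genome, fx$mask)
  expect_lt(abs(snv_mean / 1.28e-8 - 1), 1e-10)
  indel_mean <- genome_mean_indel_rate(fx$indel_models, fx$genome, fx$mask)
  expect_lt(abs(indel_mean / 0.68e-9 - 1), 1e-10)
  # generation scaling: small-rate linearization r_scaled ~ 2 n r
  r <- 1e-9
  expect_equal(scale_generations(r, 50) / (2 * 50 * r), 1, tolerance = 1e-6)
})

test_that("Monte-Carlo burden p-values match the exact Poisson-binomial", {
  set.seed(61)
  probs <- stats::runif(20, 0.001, 0.3)
  pmf <- exact_poisbinom(probs)
  for (obs in c(0, 2, 4, 7)) {
    bt <- burden_pvalue(probs, obs, n_samples = 1e5, seed = 99)
    exact_tail <- sum(pmf[(obs + 1):length(pmf)])
    se <- sqrt(exact_tail * (1 - exact_tail) / 1e5)
    expect_lt(abs(bt$p_value - exact_tail), 3 * se + 2 / 1e5)
    expect_equal(bt$expected, sum(probs))
  }
  # degenerate equal-probability case reduces to Binomial(40, 0.05)
  samples <- mutpatterns:::with_seed(
    7, mutpatterns:::sample_poisson_binomial(rep(0.05, 40), 1e5))
  n <- 40; p <- 0.05
  expect_lt(abs(mean(samples) - n * p),
            3 * sqrt(n * p * (1 - p) / 1e5))
  expect_lt(abs(stats::var(samples) - n * p * (1 - p)),
            3 * n * p * (1 - p) * sqrt(2 / 1e5) + 0.01)
  # observed = 0 always gives p = 1
  expect_equal(burden_pvalue(stats::runif(5, 0, 0.1), 0,
                             n_samples = 1e4, seed = 1)$p_value, 1)
  # reproducible under the same seed
  b1 <- burden_pvalue(probs, 3, n_samples = 1e4, seed = 5)
  b2 <- burden_pvalue(probs, 3, n_samples = 1e4, seed = 5)
  expect_identical(b1, b2)
})

test_that("generation calibration solves the monotone root", {
  expect_equal(calibrate_ngen(0.5, 0.75), 1, tolerance = 1e-6)
  # near-linear regime: doubling the target roughly doubles n_gen
  rates <- rep(1e-6, 1000)
  n1 <- calibrate_ngen(rates, 0.01)
  n2 <- calibrate_ngen(rates, 0.02)
  expect_equal(n2 / n1, 2, tolerance = 1e-3)
  # round trip on a toy exome
  set.seed(12)
  r <- stats::runif(5000, 1e-7, 1e-5)
  n_true <- 800
  target <- sum(scale_generations(r, n_true))
  expect_equal(calibrate_ngen(r, target), n_true, tolerance = 1e-5)
  expect_error(calibrate_ngen(numeric(0), 5), "zero")
  expect_error(calibrate_ngen(rep(1e-3, 10), 11), "saturation")
})

test_that("coverage correction flattens a synthetic AN bias", {
  set.seed(30)
  n <- 200
  an <- stats::runif(n, 55000, 150000)
  df <- tibble::tibble(
    transcript_id = paste0("t", 1:n), mean_an = an,
    syn_expected = stats::runif(n, 20, 60))
  # flat case: O/E = 1 everywhere -> corrections all 1
  df$syn_observed <- df$syn_expected
  flat <- coverage_correction(df, frac = 0.3)
  expect_equal(flat$correction, rep(1, n), tolerance = 1e-9)
  # linear bias in AN is removed
  bias <- an / max(an)
  df$syn_observed <- df$syn_expected * bias
  corr <- coverage_correction(df, frac = 0.3)
  oe_corr <- df$syn_observed / (df$syn_expected * corr$correction)
  slope <- stats::coef(stats::lm(oe_corr ~ an))[2] * diff(range(an))
  expect_lt(abs(slope), 0.05)
  # AN threshold drops transcripts
  df$mean_an[1] <- 40000
  kept <- coverage_correction(df, frac = 0.3)
  expect_false("t1" %in% kept$transcript_id)
  expect_error(coverage_correction(df[1:10, ]), "fewer than 20")
})

test_that("constraint scores apply the 0.5 pseudo score", {
  cs <- constraint_scores(c(0, 10, 5), c(0, 20, 5), c(0, 15, 3))
  expect_equal(cs$oe_ratio, c(1, 10.5 / 20.5, 1))
  expect_equal(cs$loeuf, c(1, 10.5 / 15.5, 5.5 / 3.5))
  expect_true(all(is.finite(unlist(cs))))
})

test_that("pooled LoF burden row sums its component categories", {
  fx <- genic_fixture()
  res <- gene_burden_test(fx$transcripts[1:2], fx$genome, fx$snv_models,
                          fx$indel_models, fx$mutations, n_gen = 1000,
                          n_samples = 1e4, seed = 5, include_lof = TRUE)
  for (id in unique(res$transcript_id)) {
    sub <- res[res$transcript_id == id, ]
    lof <- sub[sub$category == "lof", ]
    comp <- sub[sub$category %in% c("nonsense", "splice_disruption",
                                    "frameshift_indel"), ]
    expect_equal(lof$expected, sum(comp$expected))
    expect_equal(lof$observed, sum(comp$observed))
    expect_true(all(sub$p_value > 0 & sub$p_value <= 1))
    expect_true(all(sub$lower90 <= sub$upper90))
  }
})

test_that("observed mutation tallies split indels by frame", {
  fx <- genic_fixture()
  tx <- fx$transcripts[[1]]
  cpos <- mutpatterns:::cds_positions(tx)
  s <- as.character(fx$genome[[tx$chrom]])
  p <- sort(cpos)[10] + 1
  anchor <- substr(s, p, p)
  muts <- tibble::tibble(
    chrom = tx$chrom,
    pos = c(p, p),
    ref = c(anchor, paste0(anchor, substr(s, p + 1, p + 3))),
    alt = c(paste0(anchor, "AT"), anchor),
    mut_class = c("INS", "DEL"))
  obs <- observed_counts(tx, fx$genome, muts)
  expect_equal(obs$observed[obs$category == "frameshift_indel"], 1)
  expect_equal(obs$observed[obs$category == "inframe_indel"], 1)
})
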