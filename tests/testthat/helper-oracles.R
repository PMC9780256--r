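# Independent oracles used across test files. These deliberately avoid the
# package's own code paths wherever they check one.

# Top-down recursion over the reachable-partition space: single-pattern
# stats by explicit k-mer matching, children enumerated per two-partition
# table. With memo = FALSE this is a plain exhaustive recursion (feasible
# for small pattern spaces only).
oracle_partition_loss <- function(tab, alpha, cp, root, memo = TRUE) {
  mu <- mean_rate(tab)
  env <- new.env()
  f <- function(pat) {
    key <- paste(pat, collapse = "")
    if (memo && !is.null(env[[key]])) return(env[[key]])
    sel <- pattern_matches(key, tab$kmer)
    M <- sum(tab$mutated[sel])
    U <- sum(tab$background[sel])
    best <- pattern_loss(M, U, mu, alpha, cp)
    for (i in seq_along(pat)) {
      for (xy in two_partitions(pat[i])) {
        px <- pat; px[i] <- xy[1]
        py <- pat; py[i] <- xy[2]
        best <- min(best, f(px) + f(py))
      }
    }
    if (memo) env[[key]] <- best
    best
  }
  f(strsplit(root, "")[[1]])
}

# Exact Poisson-binomial pmf by sequential convolution.
exact_poisbinom <- function(probs) {
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  pmf
}

# Random count tables.
rand_snv_table <- function(seed, k = 3, central = "C", lam_m = 6,
                           lam_u = 150) {
  set.seed(seed)
  km <- all_kmers(k, central = central)
  kmer_counts(km, stats::rpois(length(km), lam_m),
              stats::rpois(length(km), lam_u),
              mut_class = paste0(central, ">T"))
}

rand_indel_table <- function(seed, k = 2, lam_m = 5, lam_u = 120) {
  set.seed(seed)
  km <- all_kmers(k)
  kmer_counts(km, stats::rpois(length(km), lam_m),
              stats::rpois(length(km), lam_u), mut_class = "DEL")
}

# Ground truth covering all six SNV classes (needed to train a full model
# set for the gene-level engine).
full_snv_truth <- function() {
  flat <- function(base, rate) {
    tibble::tibble(pattern = paste0("N", base, "N"), rate = rate)
  }
  ground_truth(
    `A>C` = flat("A", 0.001),
    `A>G` = flat("A", 0.003),
    `A>T` = flat("A", 0.001),
    `C>A` = flat("C", 0.002),
    `C>G` = flat("C", 0.002),
    `C>T` = tibble::tibble(pattern = c("NCG", "TCH", "VCT", "VCM"),
                           rate = c(0.02, 0.008, 0.004, 0.001)))
}

full_truth_with_indels <- function() {
  tr <- c(full_snv_truth(), default_indel_truth())
  class(tr) <- "ground_truth"
  tr
}

# Memoized heavy fixtures, built once per test run.
.fixture_env <- new.env()

# 1 Mb genome simulated from the 4-pattern C>T truth, counted at k = 3.
recovery_fixture <- function() {
  if (is.null(.fixture_env$recovery)) {
    sim <- simulate_genome(1e6, gc_content = 0.41, seed = 20240601)
    truth <- default_snv_truth()
    muts <- simulate_mutations(sim$genome, sim$mask, truth,
                               seed = 20240601)
    tabs <- count_snv_kmers(muts, sim$genome, sim$mask, k = 3)
    .fixture_env$recovery <- list(genome = sim$genome, mask = sim$mask,
                                  truth = truth, mutations = muts,
                                  tables = tabs)
  }
  .fixture_env$recovery
}

# Toy genome with embedded transcripts plus trained, scaled models for all
# classes; shared by the gene-level tests.
genic_fixture <- function() {
  if (is.null(.fixture_env$genic)) {
    sim <- simulate_genome(2e5, gc_content = 0.41, seed = 77)
    tr <- simulate_transcriptome(sim$genome, n_transcripts = 8, seed = 77)
    genome <- tr$genome
    mask <- full_mask(genome)
    truth <- full_truth_with_indels()
    muts <- simulate_mutations(genome, mask, truth, seed = 77)
    tabs <- count_snv_kmers(muts, genome, mask, k = 3)
    snv_models <- lapply(tabs, optimal_partition, alpha = 1, c_penalty = 5)
    itabs <- count_indel_kmers(muts, genome, mask, k_ins = 4, k_del = 5,
                               seed = 77, split_3n = TRUE)
    indel_models <- lapply(
      itabs[c("INS_3n", "INS_non3n", "DEL_3n", "DEL_non3n")],
      greedy_partition, alpha = 1, c_penalty = 10)
    .fixture_env$genic <- list(
      genome = genome, mask = mask, transcripts = tr$transcripts,
      mutations = muts,
      snv_models = scale_snv_models(snv_models, genome, mask),
      indel_models = scale_indel_models(indel_models, genome, mask))
  }
  .fixture_env$genic
}
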