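test_that("SNV counting matches hand enumeration on a toy genome", {
  gen <- as_genome(c(chr1 = "AAACAAA"))
  mut <- tibble::tibble(chrom = "chr1", pos = 4, ref = "C", alt = "G",
                        mut_class = "SNV")
  tabs <- count_snv_kmers(mut, gen, full_mask(gen), k = 3)
  at <- function(t, km, col) t[[col]][t$kmer == km]
  # windows at pos 2..6: AAA AAC ACA CAA AAA; the single C site is mutated C>G
  expect_equal(at(tabs$`C>G`, "ACA", "mutated"), 1)
  expect_equal(at(tabs$`C>G`, "ACA", "background"), 0)
  expect_equal(at(tabs$`C>A`, "ACA", "background"), 1)
  expect_equal(at(tabs$`C>T`, "ACA", "background"), 1)
  for (cl in c("A>C", "A>G", "A>T")) {
    expect_equal(sum(tabs[[cl]]$background), 4)
    expect_equal(at(tabs[[cl]], "AAA", "background"), 2)
  }
  expect_equal(sum(vapply(tabs, function(t) sum(t$mutated), 0)), 1)
})

test_that("central G/T sites are strand-collapsed onto A/C tables", {
  gen <- as_genome(c(chr1 = "TTTT"))
  none <- tibble::tibble(chrom = character(), pos = numeric(),
                         ref = character(), alt = character(),
                         mut_class = character())
  tabs <- count_snv_kmers(none, gen, full_mask(gen), 3)
  expect_equal(tabs$`A>C`$background[tabs$`A>C`$kmer == "AAA"], 2)
  for (cl in c("C>A", "C>G", "C>T")) {
    expect_equal(sum(tabs[[cl]]$background), 0)
  }
  # a T>C mutation lands in the A>G table
  gen2 <- as_genome(c(chr1 = "GGTGG"))
  mut <- tibble::tibble(chrom = "chr1", pos = 3, ref = "T", alt = "C",
                        mut_class = "SNV")
  tabs2 <- count_snv_kmers(mut, gen2, full_mask(gen2), 3)
  expect_equal(tabs2$`A>G`$mutated[tabs2$`A>G`$kmer == "CAC"], 1)
})

test_that("windows containing N are excluded from all tables", {
  gen <- as_genome(c(chr1 = "AANAA"))
  none <- tibble::tibble(chrom = character(), pos = numeric(),
                         ref = character(), alt = character(),
                         mut_class = character())
  tabs <- count_snv_kmers(none, gen, full_mask(gen), 3)
  expect_equal(sum(vapply(tabs, function(t) sum(t$background), 0)), 0)
})

test_that("site-contribution conservation holds on random genomes", {
  sim <- simulate_genome(5000, seed = 5)
  truth <- full_snv_truth()
  muts <- simulate_mutations(sim$genome, sim$mask, truth, seed = 5)
  k <- 3
  tabs <- count_snv_kmers(muts, sim$genome, sim$mask, k)
  # each N-free flankable position contributes once to u or m of each of the
  # three tables of its central base
  L <- Biostrings::width(sim$genome)[1]
  n_sites <- L - 2  # no Ns in simulated genome
  contrib <- sum(vapply(tabs, function(t) sum(t$mutated + t$background), 0))
  # mutated sites: the mutated table replaces u by m (one contribution), the
  # two sibling tables keep u, so the total is exactly 3 * sites
  expect_equal(contrib, 3 * n_sites)
  expect_equal(sum(vapply(tabs, function(t) sum(t$mutated), 0)), nrow(muts))
  # mu is exactly sum(m)/sum(m+u)
  for (t in tabs) {
    expect_identical(mean_rate(t),
                     sum(t$mutated) / (sum(t$mutated) + sum(t$background)))
  }
})

test_that("indel placement enumeration matches a brute-force edit oracle", {
  set.seed(8)
  for (trial in 1:40) {
    L <- 12
    s <- paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
    gen <- as_genome(c(c1 = s))
    len <- sample(1:3, 1)
    if (trial %% 2 == 0) {
      b0 <- sample(1:(L - 1), 1)
      ins <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      alt_seq <- paste0(substr(s, 1, b0), ins, substr(s, b0 + 1, L))
      rec <- tibble::tibble(chrom = "c1", pos = b0,
                            ref = substr(s, b0, b0),
                            alt = paste0(substr(s, b0, b0), ins),
                            mut_class = "INS")
      # an insertion at b explains the alternative sequence iff the parts of
      # the alternative outside the inserted stretch match the reference
      want <- which(vapply(0:L, function(b) {
        substr(alt_seq, 1, b) == substr(s, 1, b) &&
          substr(alt_seq, b + len + 1, L + len) == substr(s, b + 1, L)
      }, TRUE)) - 1
    } else {
      s0 <- sample(1:(L - len - 1), 1)  # 0-based start, anchor exists
      alt_seq <- paste0(substr(s, 1, s0), substr(s, s0 + len + 1, L))
      rec <- tibble::tibble(chrom = "c1", pos = s0,
                            ref = substr(s, s0, s0 + len),
                            alt = substr(s, s0, s0),
                            mut_class = "DEL")
      want <- which(vapply(0:(L - len), function(b) {
        paste0(substr(s, 1, b), substr(s, b + len + 1, L)) == alt_seq
      }, TRUE)) - 1
    }
    got <- enumerate_indel_placements(rec, gen)
    expect_setequal(got, want)
    expect_true(min(want) %in% got)  # left-aligned placement present
  }
})

test_that("indel counting conserves totals and is RC-symmetric", {
  sim <- simulate_genome(20000, seed = 13)
  truth <- default_indel_truth()
  muts <- simulate_mutations(sim$genome, sim$mask, truth, seed = 13)
  tabs <- count_indel_kmers(muts, sim$genome, sim$mask, k_ins = 4,
                            k_del = 5, seed = 13)
  n_ins <- sum(muts$mut_class == "INS")
  n_del <- sum(muts$mut_class == "DEL")
  expect_gt(n_ins, 0)
  expect_gt(n_del, 0)
  expect_equal(sum(tabs$INS$mutated), 2 * n_ins)
  expect_equal(sum(tabs$DEL$mutated), 4 * n_del)
  for (t in tabs) {
    rc <- match(revcomp(t$kmer), t$kmer)
    expect_equal(t$mutated, t$mutated[rc])
    expect_equal(t$background, t$background[rc])
  }
})

test_that("placement choice is seeded and order-invariant", {
  gen <- as_genome(c(c1 = paste0(strrep("ACGT", 20), strrep("A", 6),
                                 strrep("TGCA", 20))))
  muts <- tibble::tibble(
    chrom = "c1",
    pos = c(80, 40),
    ref = c(substr(as.character(gen[[1]]), 80, 80), "G"),
    alt = c(paste0(substr(as.character(gen[[1]]), 80, 80), "A"), "GTT"),
    mut_class = c("INS", "INS"))
  t1 <- count_indel_kmers(muts, gen, full_mask(gen), seed = 3)
  t2 <- count_indel_kmers(muts[2:1, ], gen, full_mask(gen), seed = 3)
  t3 <- count_indel_kmers(muts, gen, full_mask(gen), seed = 3)
  expect_identical(t1$INS$mutated, t2$INS$mutated)
  expect_identical(t1$INS$mutated, t3$INS$mutated)
  # the homopolymer insertion has several placements: exactly one chosen
  expect_equal(sum(t1$INS$mutated), 4)
})

test_that("argument validation", {
  gen <- as_genome(c(c1 = "ACGTACGT"))
  none <- tibble::tibble(chrom = character(), pos = numeric(),
                         ref = character(), alt = character(),
                         mut_class = character())
  expect_error(count_snv_kmers(none, gen, full_mask(gen), 4), "odd")
  expect_error(count_snv_kmers(none, gen, full_mask(gen), 13), "odd")
  long <- tibble::tibble(chrom = "c1", pos = 1, ref = "A",
                         alt = paste0("A", strrep("C", 60)),
                         mut_class = "INS")
  expect_warning(count_indel_kmers(long, gen, full_mask(gen), seed = 1),
                 "skipped")
})
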