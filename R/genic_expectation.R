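FUNCTIONAL_CATEGORIES <- c("synonymous", "missense", "nonsense",
                           "start_disruption", "stop_disruption",
                           "splice_disruption", "inframe_indel",
                           "frameshift_indel")
LOF_CATEGORIES <- c("nonsense", "splice_disruption", "frameshift_indel")

#' Construct a transcript model
#'
#' @param transcript_id Identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds Data frame of 0-based half-open genomic CDS intervals
#'   (`start`, `end`), any order; stored sorted.
#' @param genome Optional genome; when given, the CDS is validated: length a
#'   multiple of 3, ATG start and stop codon (violations warn and flag the
#'   transcript non-canonical).
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, chrom, strand, cds,
                             genome = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(cds) >= 1)
  cds <- tibble::as_tibble(cds)[, c("start", "end")]
  cds <- cds[order(cds$start), , drop = FALSE]
  stopifnot(all(cds$end > cds$start))
  if (nrow(cds) > 1 && any(cds$start[-1] < cds$end[-nrow(cds)])) {
    stop("overlapping CDS intervals", call. = FALSE)
  }
  # 2 intronic bases on each side of every internal exon boundary
  splice <- integer(0)
  if (nrow(cds) > 1) {
    prev_end <- cds$end[-nrow(cds)]
    next_start <- cds$start[-1]
    splice <- sort(unique(c(prev_end, prev_end + 1,
                            next_start - 2, next_start - 1)))
  }
  tx <- structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         cds = cds, splice_sites = splice, canonical = NA),
    class = "transcript_model")
  if (!is.null(genome)) {
    cs <- cds_seq(tx, genome)
    ok <- TRUE
    if (nchar(cs) %% 3 != 0) {
      warning(transcript_id, ": CDS length not a multiple of 3")
      ok <- FALSE
    } else {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(cs), if.fuzzy.codon = "X"))
      if (substr(cs, 1, 3) != "ATG") {
        warning(transcript_id, ": CDS does not start with ATG")
        ok <- FALSE
      }
      if (substr(aa, nchar(aa), nchar(aa)) != "*") {
        warning(transcript_id, ": CDS does not end with a stop codon")
        ok <- FALSE
      }
      if (nchar(aa) > 1 &&
          grepl("\\*", substr(aa, 1, nchar(aa) - 1))) {
        warning(transcript_id, ": internal stop codon")
        ok <- FALSE
      }
    }
    tx$canonical <- ok
  }
  tx
}

#' Coding sequence of a transcript
#'
#' @param tx A `transcript_model`.
#' @param genome A genome object.
#' @return The 5'-to-3' coding DNA string.
#' @export
cds_seq <- function(tx, genome) {
  s <- genome_seq(genome, tx$chrom)
  parts <- substring(s, tx$cds$start + 1, tx$cds$end)
  joined <- paste0(parts, collapse = "")
  if (tx$strand == "-") revcomp(joined) else joined
}

# genomic 0-based positions of CDS bases, in coding (5'->3') order
cds_positions <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i) {
    seq(tx$cds$start[i], tx$cds$end[i] - 1)
  }))
  if (tx$strand == "-") rev(pos) else pos
}

#' Read transcript models from GTF/GFF3
#'
#' CDS features are grouped by transcript id; start/stop-codon validity is
#' checked when a genome is given (violations warn and flag the transcript).
#'
#' @param path GTF or GFF3 file with CDS features.
#' @param genome Optional genome for validation.
#' @return Named list of `transcript_model` objects.
#' @export
read_transcripts <- function(path, genome = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GTF/GFF3", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  txid <- if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    as.character(unlist(mc$Parent))
  } else {
    stop("no transcript_id/Parent attribute on CDS features", call. = FALSE)
  }
  out <- list()
  for (id in unique(txid)) {
    sel <- txid == id
    out[[id]] <- transcript_model(
      id,
      chrom = as.character(GenomicRanges::seqnames(gr))[sel][1],
      strand = as.character(GenomicRanges::strand(gr))[sel][1],
      cds = tibble::tibble(start = GenomicRanges::start(gr)[sel] - 1,
                           end = as.numeric(GenomicRanges::end(gr)[sel])),
      genome = genome)
  }
  out
}

#' Classify a single-nucleotide change in a transcript
#'
#' Categories are assigned by translating the mutated codon on the coding
#' strand: synonymous, missense, nonsense (stop gain), start-codon
#' disruption (any change destroying the annotated ATG), stop-codon
#' disruption (stop to non-stop), or splice disruption (the 2 intronic
#' bases at each internal exon boundary).
#'
#' @param tx A `transcript_model`.
#' @param genome A genome object.
#' @param pos 1-based genomic position.
#' @param ref,alt Reference and alternative bases (genomic strand).
#' @return One of the functional category labels.
#' @export
classify_snv <- function(tx, genome, pos, ref, alt) {
  classify_snv_vec(tx, genome, pos, ref, alt)
}

# vectorized classifier shared by the site-table builder
classify_snv_vec <- function(tx, genome, pos, ref, alt) {
  p0 <- pos - 1
  out <- rep(NA_character_, length(pos))
  is_splice <- p0 %in% tx$splice_sites
  out[is_splice] <- "splice_disruption"
  cpos <- cds_positions(tx)
  i <- match(p0, cpos)
  if (anyNA(i[!is_splice])) {
    stop("position ", pos[!is_splice & is.na(i)][1],
         " outside CDS and splice sites of ", tx$transcript_id,
         call. = FALSE)
  }
  sel <- !is_splice
  if (!any(sel)) return(out)
  i <- i[sel]
  cs <- cds_seq(tx, genome)
  flip <- tx$strand == "-"
  ref_c <- if (flip) unname(COMPLEMENT[ref[sel]]) else ref[sel]
  alt_c <- if (flip) unname(COMPLEMENT[alt[sel]]) else alt[sel]
  if (any(substring(cs, i, i) != ref_c)) {
    stop("ref allele mismatch in ", tx$transcript_id, call. = FALSE)
  }
  codon_i <- (i - 1) %/% 3 + 1
  offset <- (i - 1) %% 3 + 1
  codon <- substring(cs, 3 * codon_i - 2, 3 * codon_i)
  new_codon <- codon
  substr2 <- function(x, at, value) {
    paste0(substr(x, 1, at - 1), value,
           substr(x, at + 1, 3))
  }
  new_codon <- substr2(codon, offset, alt_c)
  gc <- Biostrings::GENETIC_CODE
  old_aa <- unname(gc[codon])
  new_aa <- unname(gc[new_codon])
  n_codons <- nchar(cs) %/% 3
  cat <- ifelse(codon_i == 1 & codon == "ATG", "start_disruption",
         ifelse(codon_i == n_codons & old_aa == "*",
                ifelse(new_aa == "*", "synonymous", "stop_disruption"),
         ifelse(new_aa == "*", "nonsense",
         ifelse(new_aa == old_aa, "synonymous", "missense"))))
  out[sel] <- cat
  out
}

#' Scale SNV models to a target genome-wide per-generation rate
#'
#' Model rates reflect the mutation yield of the training cohort; this
#' multiplies all six class models by one factor so that the mean per-site
#' total SNV rate over the masked genome equals `target` (default
#' 1.28e-8 per base per generation).
#'
#' @param models Named list of the six SNV `pattern_partition` models.
#' @param genome,mask Genome and callable mask defining the averaging
#'   weights (each masked N-free site counts once, strand-collapsed).
#' @param target Target mean rate per base per generation.
#' @return The models with scaled rates; the factor is in attribute
#'   `scale_factor`.
#' @export
scale_snv_models <- function(models, genome, mask, target = 1.28e-8) {
  cur <- genome_mean_snv_rate(models, genome, mask)
  factor <- target / cur
  out <- lapply(models, function(m) {
    m$patterns$rate <- m$patterns$rate * factor
    m$mu <- m$mu * factor
    m
  })
  attr(out, "scale_factor") <- factor
  out
}

#' Genome-wide mean per-site SNV rate of a model set
#'
#' The count-weighted mean over all masked, N-free, k-flankable sites of
#' the site's total substitution rate (sum over the three alternative
#' bases).
#'
#' @inheritParams scale_snv_models
#' @return Numeric scalar.
#' @export
genome_mean_snv_rate <- function(models, genome, mask) {
  k <- models[[1]]$k
  stopifnot(all(vapply(models, function(m) m$k, 0L) == k))
  bg <- collapse_central(count_window_kmers(genome, mask, k), k)
  kmers <- names(bg)
  central <- substr(kmers, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
  site_rate <- numeric(length(bg))
  for (cl in names(models)) {
    base <- substr(cl, 1L, 1L)
    sel <- central == base
    site_rate[sel] <- site_rate[sel] +
      kmer_rates(models[[cl]], kmers[sel])$rate
  }
  sum(bg * site_rate) / sum(bg)
}

#' Scale indel models to a target genome-wide per-generation rate
#'
#' One factor is applied to all supplied indel models so that the mean
#' per-base indel rate (insertion breakpoint rate plus deletion rate,
#' summed over any length strata) over the masked genome equals `target`
#' (default 0.68e-9 per base per generation).
#'
#' @param models Named list of indel `pattern_partition` models (`INS`,
#'   `DEL` and/or their `_3n`/`_non3n` strata).
#' @inheritParams scale_snv_models
#' @return The models with scaled rates; factor in attribute
#'   `scale_factor`.
#' @export
scale_indel_models <- function(models, genome, mask, target = 0.68e-9) {
  cur <- genome_mean_indel_rate(models, genome, mask)
  factor <- target / cur
  out <- lapply(models, function(m) {
    m$patterns$rate <- m$patterns$rate * factor
    m$mu <- m$mu * factor
    m
  })
  attr(out, "scale_factor") <- factor
  out
}

#' Genome-wide mean per-base indel rate of a model set
#'
#' Each masked position contributes the deletion rate of its centered
#' context and the insertion rate of the breakpoint following it; the mean
#' is over positions.
#'
#' @inheritParams scale_indel_models
#' @return Numeric scalar.
#' @export
genome_mean_indel_rate <- function(models, genome, mask) {
  is_ins <- grepl("^INS", names(models))
  total <- 0
  n_pos <- NULL
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is_ins[match(nm, names(models))]) {
      bg <- count_window_kmers(genome, mask, m$k,
                               offset_left = m$k %/% 2L - 1L)
    } else {
      bg <- count_window_kmers(genome, mask, m$k)
      if (is.null(n_pos)) n_pos <- sum(bg)
    }
    total <- total + sum(bg * kmer_rates(m, names(bg))$rate)
  }
  if (is.null(n_pos)) {
    # insertion-only model set: use breakpoint count as denominator
    m <- models[[1]]
    n_pos <- sum(count_window_kmers(genome, mask, m$k,
                                    offset_left = m$k %/% 2L - 1L))
  }
  total / n_pos
}

#' Probability that a mutation occurs within n generations
#'
#' Converts a per-generation rate r into the probability of at least one
#' event over `2 * n_gen` transmitted haplotypes:
#' `r_scaled = 1 - (1 - r)^(2 n_gen)`. This keeps probabilities below 1 for
#' large cohorts.
#'
#' @param r Per-generation rate(s).
#' @param n_gen Number of observed generations.
#' @return Scaled probabilities in \[0, 1).
#' @export
scale_generations <- function(r, n_gen) {
  stopifnot(all(r >= 0), all(r < 1), n_gen >= 0)
  1 - (1 - r)^(2 * n_gen)
}

#' Enumerate every possible SNV in a transcript with category and rate
#'
#' Each CDS position contributes three entries (one per alternative base),
#' plus the canonical splice-site positions. The per-generation rate of an
#' entry is the pattern rate of its strand-collapsed context k-mer under
#' the matching class model; `r_scaled` applies the generation scaling.
#' Sites whose context window is incomplete or contains N are dropped with
#' a warning.
#'
#' @param tx A `transcript_model`.
#' @param genome A genome object.
#' @param snv_models Named list of the six (scaled) SNV models.
#' @param n_gen Number of observed generations.
#' @return A tibble: `transcript_id`, `pos` (1-based), `ref`, `alt`,
#'   `category`, `rate`, `r_scaled`.
#' @export
transcript_site_table <- function(tx, genome, snv_models, n_gen = 1) {
  k <- snv_models[[1]]$k
  cpos <- sort(c(cds_positions(tx), tx$splice_sites))
  pos1 <- cpos + 1
  s <- genome_seq(genome, tx$chrom)
  refs <- substring(s, pos1, pos1)
  bases <- c("A", "C", "G", "T")
  entries <- tibble::tibble(
    pos = rep(pos1, each = 3L),
    ref = rep(refs, each = 3L))
  entries$alt <- unlist(lapply(refs, function(b) setdiff(bases, b)))
  km <- site_kmers(genome, rep(tx$chrom, nrow(entries)), entries$pos, k)
  drop <- is.na(km)
  if (any(drop)) {
    warning(sum(drop) / 3, " site(s) of ", tx$transcript_id,
            " dropped (incomplete or N context window)")
    entries <- entries[!drop, , drop = FALSE]
    km <- km[!drop]
  }
  # strand-collapse the context for the rate lookup
  ref_c <- entries$ref
  alt_c <- entries$alt
  flip <- ref_c %in% c("G", "T")
  km[flip] <- revcomp(km[flip])
  ref_c[flip] <- COMPLEMENT[ref_c[flip]]
  alt_c[flip] <- COMPLEMENT[alt_c[flip]]
  cls <- paste0(ref_c, ">", alt_c)
  entries$rate <- NA_real_
  for (cl in unique(cls)) {
    sel <- cls == cl
    entries$rate[sel] <- kmer_rates(snv_models[[cl]], km[sel])$rate
  }
  entries$category <- classify_snv_vec(tx, genome, entries$pos,
                                       entries$ref, entries$alt)
  entries$r_scaled <- scale_generations(entries$rate, n_gen)
  tibble::tibble(transcript_id = tx$transcript_id, entries)
}

# per-breakpoint indel opportunity rates for a transcript
transcript_indel_rates <- function(tx, genome, indel_models) {
  cpos <- cds_positions(tx)
  s <- genome_seq(genome, tx$chrom)
  # inter-base breakpoints strictly inside each CDS interval
  bps <- unlist(lapply(seq_len(nrow(tx$cds)), function(i) {
    st <- tx$cds$start[i]; e <- tx$cds$end[i]
    if (e - st >= 2) seq(st + 1, e - 1) else integer(0)
  }))
  out <- list()
  for (nm in names(indel_models)) {
    m <- indel_models[[nm]]
    km <- if (grepl("^INS", nm)) {
      ins_context_str(s, bps, m$k)
    } else {
      del_context_str(s, cpos, m$k)
    }
    km <- km[!is.na(km)]
    out[[nm]] <- if (length(km)) kmer_rates(m, km)$rate else numeric(0)
  }
  out
}

#' Expected counts of each functional mutation class in a transcript
#'
#' Sums the generation-scaled probabilities of every possible SNV per
#' category; in-frame and frameshift indel expectations apply the
#' length-stratified indel models (`*_3n` to inframe, `*_non3n` to
#' frameshift) at every CDS breakpoint (inter-base positions for
#' insertions, bases for deletions).
#'
#' @inheritParams transcript_site_table
#' @param indel_models Named list of scaled indel models with `_3n` /
#'   `_non3n` strata (optional: omit for SNV categories only).
#' @return A list: `site_table` (the SNV site tibble) and `expectations`
#'   (tibble `transcript_id`, `category`, `expected`).
#' @export
expected_counts <- function(tx, genome, snv_models, indel_models = NULL,
                            n_gen = 1) {
  st <- transcript_site_table(tx, genome, snv_models, n_gen)
  exp_snv <- dplyr::summarise(
    dplyr::group_by(st, .data$category),
    expected = sum(.data$r_scaled), .groups = "drop")
  rows <- tibble::tibble(
    category = setdiff(FUNCTIONAL_CATEGORIES,
                       c("inframe_indel", "frameshift_indel")))
  rows <- dplyr::left_join(rows, exp_snv, by = "category")
  rows$expected[is.na(rows$expected)] <- 0
  if (!is.null(indel_models)) {
    strata <- names(indel_models)
    need <- c("INS_3n", "INS_non3n", "DEL_3n", "DEL_non3n")
    if (!all(need %in% strata)) {
      stop("indel_models must contain the length strata: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    ir <- transcript_indel_rates(tx, genome, indel_models[need])
    inframe <- sum(scale_generations(c(ir$INS_3n, ir$DEL_3n), n_gen))
    frameshift <- sum(scale_generations(c(ir$INS_non3n, ir$DEL_non3n),
                                        n_gen))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      category = c("inframe_indel", "frameshift_indel"),
      expected = c(inframe, frameshift)))
  }
  list(site_table = st,
       expectations = tibble::tibble(transcript_id = tx$transcript_id,
                                     rows))
}

#' Monte-Carlo burden test against the Poisson-binomial null
#'
#' Each possible mutation has its own occurrence probability, so the null
#' count distribution is Poisson-binomial; it is sampled `n_samples` times.
#' The default p-value is the add-one-corrected upper tail
#' `(1 + #\{samples >= observed\}) / (1 + n_samples)`, which never returns
#' 0. `randomize = TRUE` instead returns the randomized p-value
#' `P(X > obs) + U * P(X = obs)`, exactly uniform under the null — useful
#' for calibration studies with discrete counts.
#'
#' @param probs Per-event occurrence probabilities (the `r_scaled` column
#'   of a site table, restricted to one category).
#' @param observed Observed count (non-negative integer).
#' @param n_samples Number of Monte-Carlo samples.
#' @param seed Integer seed.
#' @param randomize Return the randomized (exactly uniform) p-value.
#' @return A one-row tibble: `expected`, `observed`, `p_value`, `lower90`,
#'   `upper90` (empirical 5th/95th percentiles of the sampled counts).
#' @export
burden_pvalue <- function(probs, observed, n_samples = 1e5, seed = 1L,
                          randomize = FALSE) {
  stopifnot(observed >= 0, n_samples >= 1e4, all(probs >= 0),
            all(probs <= 1))
  samples <- with_seed(seed, sample_poisson_binomial(probs, n_samples))
  p <- if (randomize) {
    u <- with_seed(mix_seed(seed, "randomize"), stats::runif(1))
    (sum(samples > observed) + u * (1 + sum(samples == observed))) /
      (1 + n_samples)
  } else {
    (1 + sum(samples >= observed)) / (1 + n_samples)
  }
  q <- stats::quantile(samples, c(0.05, 0.95), type = 1, names = FALSE)
  tibble::tibble(expected = sum(probs), observed = observed, p_value = p,
                 lower90 = q[1], upper90 = q[2])
}

# Exact sampler for a sum of independent Bernoulli(p_j): per site the number
# of successes across samples is Binomial(n_samples, p_j), and conditional on
# that number the successful samples are a uniform subset — so draw the
# binomial once and scatter it, instead of n_samples * n_sites uniforms.
sample_poisson_binomial <- function(probs, n_samples) {
  ks <- stats::rbinom(length(probs), n_samples, probs)
  tot <- sum(ks)
  if (tot == 0) return(integer(n_samples))
  idx <- unlist(lapply(which(ks > 0), function(j) {
    sample.int(n_samples, ks[j])
  }), use.names = FALSE)
  tabulate(idx, nbins = n_samples)
}

#' Calibrate the number of observed generations from synonymous counts
#'
#' Finds `n_gen` such that the total expected synonymous count
#' `sum(1 - (1 - r)^(2 n_gen))` equals the observed exome-wide synonymous
#' total. The expectation is strictly increasing in `n_gen`, so a monotone
#' 1-D root search converges to relative tolerance 1e-6.
#'
#' @param rates Per-generation rates of all possible synonymous mutations
#'   (pooled across transcripts).
#' @param observed_total Observed synonymous count, > 0.
#' @return The calibrated `n_gen`.
#' @export
calibrate_ngen <- function(rates, observed_total) {
  stopifnot(observed_total > 0)
  rates <- rates[rates > 0]
  if (length(rates) == 0) {
    stop("all rates are zero: target unreachable", call. = FALSE)
  }
  if (observed_total >= length(rates)) {
    stop("observed total exceeds the saturation limit (", length(rates),
         " sites)", call. = FALSE)
  }
  fn <- function(n) sum(scale_generations(rates, n)) - observed_total
  hi <- 1
  while (fn(hi) < 0) hi <- hi * 2
  root <- stats::uniroot(fn, c(0, hi), tol = 1e-9 * hi)
  # polish to relative tolerance 1e-6 of the target
  n_gen <- root$root
  stopifnot(abs(fn(n_gen)) <= 1e-6 * observed_total + 1e-9)
  n_gen
}

#' Coverage correction factors from synonymous observed/expected
#'
#' Expected counts are biased for transcripts with poor sequencing
#' coverage. A locally weighted regression (lowess, fraction `frac`) of the
#' synonymous O/E ratio on the mean allele number (AN) estimates the bias;
#' dividing each transcript's expected counts by its fitted value removes
#' it. Transcripts with mean AN at or below `an_min` are dropped.
#'
#' @param df Tibble with columns `transcript_id`, `mean_an`,
#'   `syn_observed`, `syn_expected`.
#' @param frac Lowess smoother span (fraction of the data).
#' @param an_min Minimum mean AN; transcripts at or below are excluded.
#' @return `df` restricted to retained transcripts, with a `correction`
#'   column (the lowess estimate of synonymous O/E at the transcript's AN).
#' @export
coverage_correction <- function(df, frac = 0.05, an_min = 5e4) {
  stopifnot(all(c("transcript_id", "mean_an", "syn_observed",
                  "syn_expected") %in% names(df)))
  keep <- df[df$mean_an > an_min, , drop = FALSE]
  if (nrow(keep) < 20) {
    stop("fewer than 20 transcripts above the AN threshold", call. = FALSE)
  }
  oe <- keep$syn_observed / keep$syn_expected
  lo <- stats::lowess(keep$mean_an, oe, f = frac)
  keep$correction <- stats::approx(lo$x, lo$y, xout = keep$mean_an,
                                   rule = 2, ties = mean)$y
  keep
}

#' Loss-of-function constraint scores
#'
#' LoF = nonsense + essential-splice + frameshift. The observed/expected
#' ratio uses a pseudo score of 0.5 on both counts; the conservative score
#' divides the observed count by the lower bound of the 90% interval of
#' the expected count (also with the pseudo score), so genes with little
#' data are not called constrained.
#'
#' @param lof_observed Observed LoF counts.
#' @param lof_expected (Coverage-corrected) expected LoF counts.
#' @param interval_lower Lower bound of the 90% interval of the expected
#'   count distribution.
#' @return A tibble: `lof_observed`, `lof_expected`, `oe_ratio`, `loeuf`.
#' @export
constraint_scores <- function(lof_observed, lof_expected, interval_lower) {
  stopifnot(all(lof_observed >= 0), all(lof_expected >= 0),
            all(interval_lower >= 0))
  tibble::tibble(
    lof_observed = lof_observed,
    lof_expected = lof_expected,
    oe_ratio = (lof_observed + 0.5) / (lof_expected + 0.5),
    loeuf = (lof_observed + 0.5) / (interval_lower + 0.5))
}

#' Count observed mutations per functional category in a transcript
#'
#' SNVs inside the transcript footprint are classified by
#' [classify_snv()]; indels whose anchor base lies in the CDS are
#' frameshift iff their length is not a multiple of 3.
#'
#' @param tx A `transcript_model`.
#' @param genome A genome object.
#' @param mutations Mutation tibble.
#' @return A tibble `category`, `observed` covering all 8 categories.
#' @export
observed_counts <- function(tx, genome, mutations) {
  cpos <- cds_positions(tx)
  foot <- c(cpos, tx$splice_sites)
  counts <- stats::setNames(rep(0, length(FUNCTIONAL_CATEGORIES)),
                            FUNCTIONAL_CATEGORIES)
  mut <- mutations[mutations$chrom == tx$chrom, , drop = FALSE]
  for (i in seq_len(nrow(mut))) {
    if (mut$mut_class[i] == "SNV") {
      if ((mut$pos[i] - 1) %in% foot) {
        cat <- classify_snv(tx, genome, mut$pos[i], mut$ref[i], mut$alt[i])
        counts[cat] <- counts[cat] + 1
      }
    } else {
      if ((mut$pos[i] - 1) %in% cpos) {
        len <- abs(nchar(mut$ref[i]) - nchar(mut$alt[i]))
        cat <- if (len %% 3 == 0) "inframe_indel" else "frameshift_indel"
        counts[cat] <- counts[cat] + 1
      }
    }
  }
  tibble::tibble(category = names(counts), observed = unname(counts))
}

#' Burden test for every category of every transcript
#'
#' Combines expected counts, observed counts and the Monte-Carlo
#' Poisson-binomial test. Indel categories use a Poisson-binomial over the
#' per-breakpoint opportunity probabilities.
#'
#' @param transcripts Named list of `transcript_model`s.
#' @param genome A genome object.
#' @param snv_models,indel_models Scaled models (see [scale_snv_models()]).
#' @param mutations Observed mutation tibble.
#' @param n_gen Number of observed generations.
#' @param n_samples Monte-Carlo sample count per test.
#' @param seed Integer seed.
#' @param include_lof Also test the pooled loss-of-function class
#'   (nonsense + splice disruption + frameshift), whose interval feeds the
#'   conservative constraint score. Requires `indel_models`.
#' @return A tibble: `transcript_id`, `category`, `expected`, `observed`,
#'   `p_value`, `lower90`, `upper90`.
#' @export
gene_burden_test <- function(transcripts, genome, snv_models,
                             indel_models = NULL, mutations,
                             n_gen = 1, n_samples = 1e5, seed = 1L,
                             include_lof = FALSE) {
  if (include_lof && is.null(indel_models)) {
    stop("include_lof requires indel_models", call. = FALSE)
  }
  rows <- list()
  for (tx in transcripts) {
    ec <- expected_counts(tx, genome, snv_models, indel_models, n_gen)
    obs <- observed_counts(tx, genome, mutations)
    ir <- if (!is.null(indel_models)) {
      transcript_indel_rates(tx, genome, indel_models)
    }
    cats <- ec$expectations$category
    if (include_lof) cats <- c(cats, "lof")
    for (cat in cats) {
      probs <- if (cat == "inframe_indel") {
        scale_generations(c(ir$INS_3n, ir$DEL_3n), n_gen)
      } else if (cat == "frameshift_indel") {
        scale_generations(c(ir$INS_non3n, ir$DEL_non3n), n_gen)
      } else if (cat == "lof") {
        c(ec$site_table$r_scaled[ec$site_table$category %in%
                                   c("nonsense", "splice_disruption")],
          scale_generations(c(ir$INS_non3n, ir$DEL_non3n), n_gen))
      } else {
        ec$site_table$r_scaled[ec$site_table$category == cat]
      }
      o <- if (cat == "lof") {
        sum(obs$observed[obs$category %in% LOF_CATEGORIES])
      } else {
        obs$observed[obs$category == cat]
      }
      bt <- burden_pvalue(probs, o, n_samples = n_samples,
                          seed = mix_seed(seed, tx$transcript_id, cat))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        transcript_id = tx$transcript_id, category = cat, bt)
    }
  }
  dplyr::bind_rows(rows)
}
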