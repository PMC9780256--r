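#' Ground-truth pattern model for simulation
#'
#' A named list of per-class truth tables (`pattern`, `rate`); each class's
#' patterns must partition its k-mer space (exactly-one-match) and all
#' rates must lie in (0, 1). SNV classes are keyed by collapsed k-mers
#' (central base = the class's reference base).
#'
#' @param ... Named truth tables, e.g.
#'   `` `C>T` = tibble(pattern = c("NCG", "NCH"), rate = c(0.02, 0.005)) ``.
#' @return A validated `ground_truth` list.
#' @export
ground_truth <- function(...) {
  truth <- list(...)
  stopifnot(length(truth) > 0, !is.null(names(truth)))
  for (cl in names(truth)) {
    tt <- truth[[cl]]
    stopifnot(all(c("pattern", "rate") %in% names(tt)),
              all(tt$rate > 0), all(tt$rate < 1))
    k <- unique(nchar(tt$pattern))
    stopifnot(length(k) == 1)
    space <- if (cl %in% SNV_CLASSES) {
      all_kmers(k, central = substr(cl, 1, 1))
    } else {
      all_kmers(k)
    }
    nmatch <- rowSums(vapply(tt$pattern,
                             function(p) pattern_matches(p, space),
                             logical(length(space))))
    if (!all(nmatch == 1)) {
      stop("class ", cl, ": patterns do not partition the k-mer space",
           call. = FALSE)
    }
  }
  structure(truth, class = "ground_truth")
}

#' Default SNV ground truth: a 4-pattern C>T model
#'
#' A 3-mer C>T partition with a strong CpG effect, the canonical test bed
#' for parameter recovery: NCG (CpG) > TCH > VCT > VCM.
#'
#' @return A `ground_truth` with one `C>T` class.
#' @export
default_snv_truth <- function() {
  ground_truth(
    `C>T` = tibble::tibble(
      pattern = c("NCG", "TCH", "VCT", "VCM"),
      rate = c(0.02, 0.008, 0.004, 0.001)))
}

#' Default indel ground truth
#'
#' A single-rate insertion model (4-base breakpoint context) and a
#' two-pattern deletion model (5-mer centered on the first deleted base)
#' with a higher rate at A/T centers; both are reverse-complement
#' symmetric.
#'
#' @return A `ground_truth` with `INS` and `DEL` classes.
#' @export
default_indel_truth <- function() {
  ground_truth(
    INS = tibble::tibble(pattern = "NNNN", rate = 4e-4),
    DEL = tibble::tibble(pattern = c("NNWNN", "NNSNN"),
                         rate = c(8e-4, 3e-4)))
}

truth_rate_lookup <- function(tt) {
  expanded <- lapply(tt$pattern, expand_pattern)
  stats::setNames(rep(tt$rate, lengths(expanded)), unlist(expanded))
}

#' Simulate an i.i.d. random genome with full-coverage mask
#'
#' @param length Chromosome length (>= 1000).
#' @param gc_content Fraction of G+C bases (default 0.41, human-like).
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (`length` each).
#' @return A list: `genome` (DNAStringSet), `mask` (full-coverage
#'   `region_mask`).
#' @export
simulate_genome <- function(length, gc_content = 0.41, seed = 1L,
                            n_chrom = 1L) {
  stopifnot(length >= 1000, gc_content >= 0, gc_content <= 1)
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  seqs <- with_seed(mix_seed(seed, "genome"), {
    vapply(seq_len(n_chrom), function(i) {
      paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = p), collapse = "")
    }, "")
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  genome <- as_genome(seqs)
  list(genome = genome, mask = full_mask(genome))
}

#' Simulate mutations from a ground-truth pattern model
#'
#' Every masked site (SNV classes) or breakpoint (indels) mutates
#' independently with the rate of the truth pattern matching its context;
#' at most one mutation is placed per site. The output record order is
#' shuffled.
#'
#' @param genome A genome object.
#' @param mask A `region_mask`.
#' @param truth A `ground_truth`.
#' @param seed Integer seed.
#' @param indel_lengths Candidate indel lengths (sampled uniformly).
#' @return A mutation tibble (`chrom`, `pos`, `ref`, `alt`, `mut_class`).
#' @export
simulate_mutations <- function(genome, mask, truth, seed = 1L,
                               indel_lengths = 1:3) {
  snv_classes <- intersect(names(truth), SNV_CLASSES)
  recs <- list()
  for (chrom in unique(mask$chrom)) {
    s <- genome_seq(genome, chrom)
    L <- nchar(s)
    iv <- mask[mask$chrom == chrom, , drop = FALSE]
    pos1 <- unlist(lapply(seq_len(nrow(iv)), function(i) {
      seq(iv$start[i] + 1, iv$end[i])
    }))

    if (length(snv_classes)) {
      k <- nchar(truth[[snv_classes[1]]]$pattern[1])
      w <- (k - 1L) %/% 2L
      ok <- pos1 - w >= 1 & pos1 + w <= L
      p_snv <- pos1[ok]
      km <- substring(s, p_snv - w, p_snv + w)
      good <- !grepl("N", km)
      p_snv <- p_snv[good]
      km <- km[good]
      ref <- substring(s, p_snv, p_snv)
      flip <- ref %in% c("G", "T")
      kmc <- km
      kmc[flip] <- revcomp(km[flip])
      # per-site class probabilities, collapsed representation
      pm <- matrix(0, length(p_snv), length(snv_classes))
      central <- COMPLEMENT[ref]
      central[!flip] <- ref[!flip]
      for (j in seq_along(snv_classes)) {
        cl <- snv_classes[j]
        lk <- truth_rate_lookup(truth[[cl]])
        sel <- central == substr(cl, 1, 1)
        pm[sel, j] <- lk[kmc[sel]]
      }
      draws <- with_seed(mix_seed(seed, "snv", chrom),
                         stats::runif(length(p_snv)))
      cum <- if (ncol(pm) == 1L) pm else t(apply(pm, 1, cumsum))
      hit <- draws < cum[, ncol(cum)]
      which_cl <- max.col(draws < cum, ties.method = "first")
      if (any(hit)) {
        cls <- snv_classes[which_cl[hit]]
        alt_coll <- substr(cls, 3, 3)
        alt <- ifelse(flip[hit], COMPLEMENT[alt_coll], alt_coll)
        recs[[length(recs) + 1L]] <- tibble::tibble(
          chrom = chrom, pos = p_snv[hit], ref = ref[hit],
          alt = unname(alt), mut_class = "SNV")
      }
    }

    if ("INS" %in% names(truth)) {
      k_ins <- nchar(truth$INS$pattern[1])
      hw <- k_ins %/% 2L
      bps <- pos1  # breakpoint after each masked position
      ok <- bps - hw >= 0 & bps + hw <= L & bps >= 1
      bps <- bps[ok]
      ctx <- substring(s, bps - hw + 1, bps + hw)
      good <- !grepl("N", ctx)
      bps <- bps[good]
      ctx <- ctx[good]
      lk <- truth_rate_lookup(truth$INS)
      hit <- with_seed(mix_seed(seed, "ins", chrom),
                       stats::runif(length(bps))) < lk[ctx]
      if (any(hit)) {
        b <- bps[hit]
        ins <- with_seed(mix_seed(seed, "ins-seq", chrom), {
          vapply(seq_along(b), function(i) {
            paste0(sample(c("A", "C", "G", "T"),
                          sample(indel_lengths, 1), replace = TRUE),
                   collapse = "")
          }, "")
        })
        anchor <- substring(s, b, b)
        recs[[length(recs) + 1L]] <- tibble::tibble(
          chrom = chrom, pos = b, ref = anchor,
          alt = paste0(anchor, ins), mut_class = "INS")
      }
    }

    if ("DEL" %in% names(truth)) {
      k_del <- nchar(truth$DEL$pattern[1])
      w <- (k_del - 1L) %/% 2L
      starts <- pos1  # 1-based first deleted base
      maxlen <- max(indel_lengths)
      ok <- starts - w >= 1 & starts + w <= L & starts >= 2 &
        starts + maxlen - 1 <= L
      starts <- starts[ok]
      ctx <- substring(s, starts - w, starts + w)
      good <- !grepl("N", ctx)
      starts <- starts[good]
      ctx <- ctx[good]
      lk <- truth_rate_lookup(truth$DEL)
      hit <- with_seed(mix_seed(seed, "del", chrom),
                       stats::runif(length(starts))) < lk[ctx]
      if (any(hit)) {
        st <- starts[hit]
        lens <- with_seed(mix_seed(seed, "del-len", chrom),
                          sample(rep(indel_lengths, 2), length(st),
                                 replace = TRUE))
        deleted <- substring(s, st, st + lens - 1)
        bad <- grepl("N", deleted)
        anchor <- substring(s, st - 1, st - 1)
        recs[[length(recs) + 1L]] <- tibble::tibble(
          chrom = chrom, pos = st - 1, ref = paste0(anchor, deleted),
          alt = anchor, mut_class = "DEL")[!bad, ]
      }
    }
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          ref = character(), alt = character(),
                          mut_class = character()))
  }
  out[with_seed(mix_seed(seed, "shuffle"), sample.int(nrow(out))), ]
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T"), stringsAsFactors = FALSE),
        1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Simulate a toy transcriptome embedded in a genome
#'
#' Generates non-overlapping multi-exon protein-coding transcripts (ATG
#' start, stop codon, no internal stop, GT–AG introns) on both strands and
#' writes their sequences into the genome.
#'
#' @param genome A genome object (modified copy returned).
#' @param n_transcripts Number of transcripts.
#' @param seed Integer seed.
#' @param n_codons_range,intron_range,n_exons_range Size ranges sampled per
#'   transcript.
#' @return A list: `genome` (with transcripts embedded), `transcripts`
#'   (named list of validated `transcript_model`s).
#' @export
simulate_transcriptome <- function(genome, n_transcripts = 5L, seed = 1L,
                                   n_codons_range = c(40L, 120L),
                                   intron_range = c(60L, 150L),
                                   n_exons_range = c(2L, 4L)) {
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]
  gs <- genome_seq(genome, chrom)
  specs <- list()
  with_seed(mix_seed(seed, "transcriptome"), {
    cursor <- 200L
    for (t in seq_len(n_transcripts)) {
      n_codons <- sample(seq(n_codons_range[1], n_codons_range[2]), 1)
      n_exons <- sample(seq(n_exons_range[1], n_exons_range[2]), 1)
      cds <- paste0("ATG",
                    paste0(sample(NONSTOP_CODONS, n_codons, replace = TRUE),
                           collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1))
      clen <- nchar(cds)
      # split CDS into exon pieces of >= 6 bases
      cuts <- sort(sample(seq(6, clen - 6), n_exons - 1))
      cuts <- unique(c(0, cuts, clen))
      n_exons <- length(cuts) - 1
      exon_seqs <- substring(cds, cuts[-length(cuts)] + 1, cuts[-1])
      introns <- vapply(seq_len(n_exons - 1), function(i) {
        len <- sample(seq(intron_range[1], intron_range[2]), 1)
        paste0("GT", paste0(sample(c("A", "C", "G", "T"), len - 4,
                                   replace = TRUE), collapse = ""), "AG")
      }, "")
      pieces <- character(0)
      t_starts <- integer(n_exons)
      t_ends <- integer(n_exons)
      at <- 0L
      for (i in seq_len(n_exons)) {
        t_starts[i] <- at
        at <- at + nchar(exon_seqs[i])
        t_ends[i] <- at
        pieces <- c(pieces, exon_seqs[i])
        if (i < n_exons) {
          pieces <- c(pieces, introns[i])
          at <- at + nchar(introns[i])
        }
      }
      pre <- paste0(pieces, collapse = "")
      seg_len <- nchar(pre)
      strand <- sample(c("+", "-"), 1)
      seg_start <- cursor  # 0-based
      if (seg_start + seg_len + 200 > L) {
        warning("genome too short: placed ", t - 1, " of ",
                n_transcripts, " transcripts")
        break
      }
      seg <- if (strand == "-") revcomp(pre) else pre
      substr(gs, seg_start + 1, seg_start + seg_len) <- seg
      cds_iv <- if (strand == "+") {
        tibble::tibble(start = seg_start + t_starts,
                       end = seg_start + t_ends)
      } else {
        tibble::tibble(start = seg_start + seg_len - t_ends,
                       end = seg_start + seg_len - t_starts)
      }
      specs[[paste0("tx", t)]] <- list(strand = strand, cds = cds_iv)
      cursor <- seg_start + seg_len + sample(100:300, 1)
    }
  })
  newgen <- stats::setNames(as.character(genome), names(genome))
  newgen[chrom] <- gs
  genome <- as_genome(newgen)
  out_tx <- lapply(names(specs), function(id) {
    transcript_model(id, chrom, specs[[id]]$strand, specs[[id]]$cds,
                     genome = genome)
  })
  names(out_tx) <- names(specs)
  list(genome = genome, transcripts = out_tx)
}

#' Write transcript models as GTF
#'
#' One CDS feature per coding interval, with gene_id/transcript_id
#' attributes and correct frame fields.
#'
#' @param transcripts Named list of `transcript_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    iv <- tx$cds
    ord <- if (tx$strand == "+") order(iv$start) else order(-iv$start)
    cum <- 0L
    frame <- integer(nrow(iv))
    for (i in ord) {
      frame[i] <- (3 - cum %% 3) %% 3
      cum <- cum + (iv$end[i] - iv$start[i])
    }
    lines <- c(lines, sprintf(
      "%s\tmutpatterns\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id \"%s\"; transcript_id \"%s\";",
      tx$chrom, iv$start + 1, iv$end, tx$strand, frame,
      paste0("g_", tx$transcript_id), tx$transcript_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome A genome object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write a mask to BED3
#'
#' @param mask A `region_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  writeLines(sprintf("%s\t%d\t%d", mask$chrom, as.integer(mask$start),
                     as.integer(mask$end)), path)
  invisible(path)
}
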