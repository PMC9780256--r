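#' @title k-mer count tables
#' @description A `kmer_counts` object is a tibble with columns `kmer`,
#'   `mutated` (m) and `background` (u), one row per k-mer, carrying the
#'   k-mer size and mutation class as attributes. It is the input of the
#'   pattern-partition optimizer.
#' @name kmer_counts
NULL

SNV_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")

new_kmer_counts <- function(kmer, mutated, background, k, mut_class) {
  out <- tibble::tibble(kmer = kmer, mutated = as.numeric(mutated),
                        background = as.numeric(background))
  structure(out, k = as.integer(k), mut_class = mut_class,
            class = c("kmer_counts", class(tibble::tibble())))
}

#' Build a k-mer count table from vectors
#'
#' @param kmer Character vector of k-mers.
#' @param mutated,background Non-negative counts (m and u per k-mer).
#' @param mut_class Label of the mutation class (e.g. `"C>T"`, `"INS"`).
#' @return A `kmer_counts` tibble.
#' @export
kmer_counts <- function(kmer, mutated, background, mut_class = "SNV") {
  stopifnot(length(kmer) == length(mutated),
            length(kmer) == length(background),
            all(mutated >= 0), all(background >= 0),
            !anyDuplicated(kmer))
  k <- unique(nchar(kmer))
  stopifnot(length(k) == 1L)
  new_kmer_counts(kmer, mutated, background, k, mut_class)
}

#' Overall mutation rate of a count table
#'
#' The mean rate mu = sum(m) / sum(m + u), the anchor of the regularized
#' per-pattern rate estimate.
#'
#' @param table A `kmer_counts` object.
#' @return Numeric scalar in \[0, 1\].
#' @export
mean_rate <- function(table) {
  tot <- sum(table$mutated) + sum(table$background)
  if (tot == 0) return(NaN)
  sum(table$mutated) / tot
}

# Count all k-length windows centered at masked positions (flanks may extend
# outside the mask but not past chromosome ends; windows containing N are
# dropped by the counter). Returns a named count vector over all 4^k k-mers.
count_window_kmers <- function(genome, mask, k, offset_left = (k - 1L) %/% 2L) {
  w_l <- offset_left
  w_r <- k - 1L - w_l
  segs <- character(0)
  for (chrom in unique(mask$chrom)) {
    s <- genome_seq(genome, chrom)
    L <- nchar(s)
    iv <- mask[mask$chrom == chrom, , drop = FALSE]
    from <- pmax(1, iv$start + 1 - w_l)
    to <- pmin(L, iv$end + w_r)
    keep <- to - from + 1 >= k
    segs <- c(segs, substring(s, from[keep], to[keep]))
  }
  if (length(segs) == 0L) {
    z <- rep(0, 4^k)
    names(z) <- all_kmers(k)
    return(z)
  }
  freq <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(segs), width = k, step = 1L)
  counts <- colSums(freq)
  counts[all_kmers(k)]
}

# Collapse a full 4^k count vector onto k-mers with central base A or C by
# adding each G/T-central k-mer's count to its reverse complement.
collapse_central <- function(counts, k) {
  kmers <- names(counts)
  central <- substr(kmers, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
  keep <- central %in% c("A", "C")
  flip <- counts[!keep]
  out <- counts[keep]
  if (length(flip)) {
    rc <- revcomp(names(flip))
    agg <- tapply(as.numeric(flip), rc, sum)
    out[names(agg)] <- out[names(agg)] + agg
  }
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Extract the k-mer centered at 1-based position pos of each record's
# chromosome; NA where the window is incomplete or contains N.
site_kmers <- function(genome, chrom, pos, k) {
  w <- (k - 1L) %/% 2L
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    s <- genome_seq(genome, ch)
    L <- nchar(s)
    i <- which(chrom == ch)
    ok <- pos[i] - w >= 1 & pos[i] + w <= L
    km <- rep(NA_character_, length(i))
    km[ok] <- substring(s, pos[i][ok] - w, pos[i][ok] + w)
    km[!is.na(km) & grepl("N", km)] <- NA_character_
    out[i] <- km
  }
  out
}

#' Count mutated and background k-mers for the six SNV classes
#'
#' Every masked position whose full k-mer window is N-free contributes one
#' background opportunity to each of the three substitution tables sharing
#' its central base; positions (and alleles) with central base G or T are
#' reverse-complemented first, so all tables are keyed by k-mers with
#' central A or C. Each observed SNV adds 1 to the mutated count of exactly
#' one table and its site is removed once from that table's background.
#'
#' @param mutations Mutation tibble (only SNV rows are used); should already
#'   be filtered to the mask.
#' @param genome A genome object.
#' @param mask A `region_mask` of callable positions.
#' @param k Odd k-mer size, 1–11.
#' @return Named list of six `kmer_counts` tables
#'   (`A>C`, `A>G`, `A>T`, `C>A`, `C>G`, `C>T`).
#' @export
count_snv_kmers <- function(mutations, genome, mask, k) {
  if (k %% 2L != 1L || k < 1L || k > 11L) {
    stop("k must be odd and between 1 and 11", call. = FALSE)
  }
  bg <- collapse_central(count_window_kmers(genome, mask, k), k)
  central <- substr(names(bg), (k + 1L) %/% 2L, (k + 1L) %/% 2L)
  bg_by_base <- split(bg, central)

  snv <- mutations[mutations$mut_class == "SNV", , drop = FALSE]
  km <- site_kmers(genome, snv$chrom, snv$pos, k)
  ref <- snv$ref
  alt <- snv$alt
  flip <- ref %in% c("G", "T") & !is.na(km)
  km[flip] <- revcomp(km[flip])
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  cls <- paste0(ref, ">", alt)
  valid <- !is.na(km)
  if (any(!valid)) {
    n_bad <- sum(!valid)
    if (n_bad > 0) message(n_bad, " SNV(s) skipped (incomplete or N window)")
  }

  # one background decrement per unique mutated site per table
  site_key <- paste(snv$chrom, snv$pos, cls)
  first <- !duplicated(site_key) & valid

  out <- list()
  for (cl in SNV_CLASSES) {
    base <- substr(cl, 1L, 1L)
    u <- bg_by_base[[base]]
    if (is.null(u)) {
      u <- rep(0, 4^(k - 1L))
      names(u) <- all_kmers(k, central = base)
    }
    m <- rep(0, length(u))
    names(m) <- names(u)
    sel <- valid & cls == cl
    if (any(sel)) {
      tab <- table(km[sel])
      m[names(tab)] <- m[names(tab)] + as.numeric(tab)
      dec <- table(km[sel & first])
      u[names(dec)] <- pmax(0, u[names(dec)] - as.numeric(dec))
    }
    ord <- all_kmers(k, central = base)
    out[[cl]] <- new_kmer_counts(ord, m[ord], u[ord], k, cl)
  }
  out
}

#' Enumerate equivalent placements of an indel
#'
#' An indel's position is often indeterminable: several distinct breakpoints
#' can produce the same alternative sequence (e.g. inserting an A anywhere
#' inside a homopolymer run). This returns every 0-based breakpoint at which
#' applying the edit yields a chromosome identical to the observed one.
#' For insertions a breakpoint is the inter-base index (number of bases to
#' the left); for deletions it is the index of the first deleted base.
#'
#' @param record One-row mutation tibble (INS or DEL).
#' @param genome A genome object.
#' @return Sorted integer vector of equivalent breakpoints; always contains
#'   the left-aligned placement.
#' @export
enumerate_indel_placements <- function(record, genome) {
  stopifnot(nrow(record) == 1L, record$mut_class %in% c("INS", "DEL"))
  placements_in_string(record, genome_seq(genome, record$chrom))
}

placements_in_string <- function(record, s) {
  L <- nchar(s)
  base_at <- function(i) substr(s, i + 1L, i + 1L)  # 0-based lookup
  if (record$mut_class == "INS") {
    ins <- substr(record$alt, 2L, nchar(record$alt))
    len <- nchar(ins)
    b0 <- as.integer(record$pos)  # insertion after 1-based pos => interbase b0
    ichar <- strsplit(ins, "")[[1]]
    bps <- b0
    # shift right: placement b+1 equivalent iff base after b equals the
    # rotating first character of the insertion
    rot <- 0L; b <- b0
    while (b < L && base_at(b) == ichar[(rot %% len) + 1L]) {
      b <- b + 1L; rot <- rot + 1L; bps <- c(bps, b)
    }
    # shift left: placement b-1 equivalent iff base before b equals the
    # rotating last character
    rot <- 0L; b <- b0
    while (b > 0L && base_at(b - 1L) == ichar[len - (rot %% len)]) {
      b <- b - 1L; rot <- rot + 1L; bps <- c(bps, b)
    }
  } else {
    len <- nchar(record$ref) - 1L
    s0 <- as.integer(record$pos)  # first deleted base, 0-based
    bps <- s0
    b <- s0
    while (b + len < L && base_at(b) == base_at(b + len)) {
      b <- b + 1L; bps <- c(bps, b)
    }
    b <- s0
    while (b > 0L && base_at(b - 1L) == base_at(b + len - 1L)) {
      b <- b - 1L; bps <- c(bps, b)
    }
  }
  sort(unique(bps))
}

# deterministic uniform choice among n placements for one record
choose_placement <- function(seed, record, n) {
  h <- mix_seed(seed, record$chrom, record$pos, record$ref, record$alt)
  (h %% n) + 1L
}

# breakpoint context: k/2 bases left + k/2 bases right of interbase b;
# vectorized over b, NA where incomplete or containing N
ins_context_str <- function(s, b, k) {
  hw <- k %/% 2L
  km <- ifelse(b - hw < 0L | b + hw > nchar(s), NA_character_,
               substring(s, b - hw + 1L, b + hw))
  km[!is.na(km) & grepl("N", km)] <- NA_character_
  km
}

# odd k-mer centered on a 0-based base index; vectorized
del_context_str <- function(s, center0, k) {
  w <- (k - 1L) %/% 2L
  p <- center0 + 1L
  km <- ifelse(p - w < 1L | p + w > nchar(s), NA_character_,
               substring(s, p - w, p + w))
  km[!is.na(km) & grepl("N", km)] <- NA_character_
  km
}

add_with_rc <- function(vec, kmers) {
  kmers <- kmers[!is.na(kmers)]
  if (length(kmers) == 0L) return(vec)
  tab <- table(c(kmers, revcomp(kmers)))
  vec[names(tab)] <- vec[names(tab)] + as.numeric(tab)
  vec
}

#' Count breakpoint-context k-mers for insertions and deletions
#'
#' For each indel, one of its equivalent placements is chosen uniformly at
#' random; the choice is derived from the seed and the record's own
#' coordinates, so it is reproducible and independent of record order.
#' Insertions contribute the inter-base breakpoint context (an even k-mer:
#' `k_ins/2` bases on each side) and its reverse complement. Deletions
#' contribute the odd k-mer centered on the first deleted base (start
#' breakpoint) and on the last deleted base (end breakpoint), each with its
#' reverse complement — the reverse complement of a start k-mer is an end
#' k-mer, so one combined DEL table covers both orientations. Background
#' counts cover every masked breakpoint position's context the same way.
#'
#' @param mutations Mutation tibble (INS/DEL rows used), filtered to mask.
#' @param genome A genome object.
#' @param mask A `region_mask`.
#' @param k_ins Even context size for insertions.
#' @param k_del Odd context size for deletions.
#' @param seed Integer seed controlling placement choices.
#' @param split_3n If `TRUE`, also return length-stratified tables
#'   (`INS_3n`, `INS_non3n`, `DEL_3n`, `DEL_non3n`).
#' @param max_len Indels longer than this are skipped with a warning.
#' @return Named list of `kmer_counts` tables (`INS`, `DEL`, and the 3n
#'   splits when requested).
#' @export
count_indel_kmers <- function(mutations, genome, mask, k_ins = 4L,
                              k_del = 5L, seed = 1L, split_3n = FALSE,
                              max_len = 50L) {
  stopifnot(k_ins %% 2L == 0L, k_ins >= 2L, k_del %% 2L == 1L, k_del >= 1L)
  ind <- mutations[mutations$mut_class %in% c("INS", "DEL"), , drop = FALSE]
  lens <- abs(nchar(ind$ref) - nchar(ind$alt))
  if (any(lens > max_len)) {
    warning(sum(lens > max_len), " indel(s) longer than ", max_len,
            " bp skipped")
    ind <- ind[lens <= max_len, , drop = FALSE]
    lens <- lens[lens <= max_len]
  }

  # background: every masked breakpoint's context plus reverse complement
  ins_bg <- count_window_kmers(genome, mask, k_ins,
                               offset_left = k_ins %/% 2L - 1L)
  ins_bg <- ins_bg + ins_bg[revcomp(names(ins_bg))]
  del_bg <- count_window_kmers(genome, mask, k_del)
  del_bg <- del_bg + del_bg[revcomp(names(del_bg))]

  chrom_str <- lapply(
    stats::setNames(nm = unique(ind$chrom)),
    function(ch) genome_seq(genome, ch))

  ins_m <- function(rows) {
    m <- rep(0, length(ins_bg)); names(m) <- names(ins_bg)
    kms <- character(0)
    for (i in rows) {
      rec <- ind[i, , drop = FALSE]
      s <- chrom_str[[rec$chrom]]
      bps <- placements_in_string(rec, s)
      b <- bps[choose_placement(seed, rec, length(bps))]
      kms <- c(kms, ins_context_str(s, b, k_ins))
    }
    add_with_rc(m, kms)
  }
  del_m <- function(rows) {
    m <- rep(0, length(del_bg)); names(m) <- names(del_bg)
    kms <- character(0)
    for (i in rows) {
      rec <- ind[i, , drop = FALSE]
      s <- chrom_str[[rec$chrom]]
      len <- nchar(rec$ref) - 1L
      bps <- placements_in_string(rec, s)
      b <- bps[choose_placement(seed, rec, length(bps))]
      kms <- c(kms, del_context_str(s, b, k_del),
               del_context_str(s, b + len - 1L, k_del))
    }
    add_with_rc(m, kms)
  }

  is_ins <- ind$mut_class == "INS"
  out <- list(
    INS = new_kmer_counts(names(ins_bg), ins_m(which(is_ins)), ins_bg,
                          k_ins, "INS"),
    DEL = new_kmer_counts(names(del_bg), del_m(which(!is_ins)), del_bg,
                          k_del, "DEL")
  )
  if (split_3n) {
    n3 <- lens %% 3L == 0L
    out$INS_3n <- new_kmer_counts(names(ins_bg), ins_m(which(is_ins & n3)),
                                  ins_bg, k_ins, "INS_3n")
    out$INS_non3n <- new_kmer_counts(names(ins_bg),
                                     ins_m(which(is_ins & !n3)),
                                     ins_bg, k_ins, "INS_non3n")
    out$DEL_3n <- new_kmer_counts(names(del_bg), del_m(which(!is_ins & n3)),
                                  del_bg, k_del, "DEL_3n")
    out$DEL_non3n <- new_kmer_counts(names(del_bg),
                                     del_m(which(!is_ins & !n3)),
                                     del_bg, k_del, "DEL_non3n")
  }
  out
}
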