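#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated to contain only A/C/G/T/N.
#' Chromosome names are taken as the first whitespace-delimited token of each
#' FASTA header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_genome(seqs)
}

#' Coerce to a validated genome object
#'
#' @param x A named character vector or [Biostrings::DNAStringSet].
#' @return A validated uppercase [Biostrings::DNAStringSet].
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    chr <- stats::setNames(as.character(x), names(x))
  } else {
    stopifnot(is.character(x))
    chr <- x
  }
  if (is.null(names(chr)) || anyNA(names(chr)) || any(names(chr) == "")) {
    stop("genome sequences must be named by chromosome", call. = FALSE)
  }
  if (anyDuplicated(names(chr))) {
    stop("duplicated chromosome names in genome", call. = FALSE)
  }
  chr <- toupper(chr)
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    stop("genome contains non-ACGTN characters in: ",
         paste(names(chr)[bad], collapse = ", "), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(chr)
  out
}

genome_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    stop("chromosome not in genome: ", chrom, call. = FALSE)
  }
  as.character(genome[[chrom]])
}

#' Construct a region mask
#'
#' A region mask is a per-chromosome set of 0-based half-open intervals.
#' Overlapping or adjacent input intervals are unioned; intervals are stored
#' sorted. The callable-region mask restricting mutation counting is the main
#' use.
#'
#' @param intervals A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A tibble of class `region_mask` with sorted, disjoint intervals.
#' @export
region_mask <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  df <- tibble::as_tibble(intervals)[, c("chrom", "start", "end")]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start < 0)) stop("negative interval start", call. = FALSE)
  if (any(df$end <= df$start)) {
    stop("empty or inverted interval (end <= start)", call. = FALSE)
  }
  gr <- GenomicRanges::reduce(mask_to_granges(df))
  new_region_mask(granges_to_tbl(gr))
}

new_region_mask <- function(df) {
  structure(df, class = c("region_mask", class(tibble::tibble())))
}

mask_to_granges <- function(mask) {
  GenomicRanges::GRanges(
    seqnames = mask$chrom,
    ranges = IRanges::IRanges(start = mask$start + 1, end = mask$end)
  )
}

granges_to_tbl <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Total number of bases covered by a mask
#'
#' @param mask A `region_mask`.
#' @return Numeric scalar: the sum of interval lengths.
#' @export
mask_size <- function(mask) {
  sum(mask$end - mask$start)
}

#' Read a BED3 file into a region mask
#'
#' @param path Path to a BED file (0-based half-open, >= 3 columns).
#' @return A `region_mask`; overlapping input intervals are unioned.
#' @export
read_mask <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_region_mask(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric())))
  }
  fields <- strsplit(lines, "\t| +")
  n <- vapply(fields, length, 1L)
  if (any(n < 3L)) {
    stop("malformed BED line (fewer than 3 columns) at line ",
         which(n < 3L)[1], call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric BED coordinate at line ",
         which(is.na(start) | is.na(end))[1], call. = FALSE)
  }
  if (any(end <= start)) {
    stop("BED interval with end <= start at line ",
         which(end <= start)[1], call. = FALSE)
  }
  region_mask(tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L), start = start, end = end))
}

#' Subtract one mask from another
#'
#' Returns the bases in `a` that are not in `b` — e.g. removing excluded
#' regions (such as hypermutated clusters) from a callable mask.
#'
#' @param a,b `region_mask` objects.
#' @return A `region_mask` covering exactly `a \ b`.
#' @export
subtract_mask <- function(a, b) {
  gr <- GenomicRanges::setdiff(mask_to_granges(a), mask_to_granges(b))
  new_region_mask(granges_to_tbl(gr))
}

#' Intersect two masks
#'
#' @param a,b `region_mask` objects.
#' @return A `region_mask` covering exactly the bases in both.
#' @export
intersect_mask <- function(a, b) {
  gr <- GenomicRanges::intersect(mask_to_granges(a), mask_to_granges(b))
  new_region_mask(granges_to_tbl(gr))
}

#' Full-coverage mask for a genome
#'
#' @param genome A genome ([Biostrings::DNAStringSet]).
#' @return A `region_mask` covering every base of every chromosome.
#' @export
full_mask <- function(genome) {
  region_mask(tibble::tibble(
    chrom = names(genome), start = 0,
    end = as.numeric(Biostrings::width(genome))))
}

classify_alleles <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L & ref != alt ~ "SNV",
    nchar(ref) == 1L & nchar(alt) > 1L &
      substr(alt, 1L, 1L) == ref ~ "INS",
    nchar(alt) == 1L & nchar(ref) > 1L &
      substr(ref, 1L, 1L) == alt ~ "DEL",
    TRUE ~ NA_character_
  )
}

#' Read observed mutations from VCF or TSV
#'
#' Accepts a VCF 4.x file or a headered TSV with columns
#' `chrom`, `pos` (1-based), `ref`, `alt`. Multi-allelic VCF records are
#' split into one record per alternative allele. Records are classified as
#' SNV, INS (anchor-base insertion) or DEL (anchor-base deletion); symbolic
#' alleles, non-ACGT alleles and complex substitutions are skipped with a
#' warning. When a genome is supplied, records whose `ref` does not match
#' the genome are rejected and the count reported.
#'
#' @param path Input file.
#' @param genome Optional genome for reference-allele checking.
#' @param normalize_chrom If `TRUE`, "chr" prefixes are harmonized with the
#'   genome's naming; default is strict matching.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `mut_class`.
#' @export
read_mutations <- function(path, genome = NULL, normalize_chrom = FALSE) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path)
  if (is_vcf) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("vcfR is required to read VCF files", call. = FALSE)
    }
    fix <- suppressWarnings(
      vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE)))
    if (is.null(dim(fix))) {
      fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    }
    df <- tibble::tibble(
      chrom = as.character(fix[, "CHROM"]),
      pos = as.numeric(fix[, "POS"]),
      ref = toupper(as.character(fix[, "REF"])),
      alt = toupper(as.character(fix[, "ALT"]))
    )
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE,
                          progress = FALSE)
    names(df) <- tolower(names(df))
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
    df <- tibble::tibble(chrom = as.character(df$chrom),
                         pos = as.numeric(df$pos),
                         ref = toupper(df$ref), alt = toupper(df$alt))
  }
  # split multi-allelic records
  df <- tidyr::separate_rows(df, "alt", sep = ",")
  symbolic <- grepl("[][<>*.]", df$alt) | grepl("[][<>*.]", df$ref)
  if (any(symbolic)) {
    warning(sum(symbolic), " symbolic/structural allele(s) skipped")
    df <- df[!symbolic, , drop = FALSE]
  }
  bad_chars <- grepl("[^ACGT]", df$ref) | grepl("[^ACGT]", df$alt)
  if (any(bad_chars)) {
    warning(sum(bad_chars), " record(s) with non-ACGT alleles skipped")
    df <- df[!bad_chars, , drop = FALSE]
  }
  df$mut_class <- classify_alleles(df$ref, df$alt)
  if (anyNA(df$mut_class)) {
    warning(sum(is.na(df$mut_class)),
            " complex substitution record(s) skipped")
    df <- df[!is.na(df$mut_class), , drop = FALSE]
  }
  if (!is.null(genome)) {
    if (normalize_chrom) {
      has_chr <- any(grepl("^chr", names(genome)))
      df$chrom <- if (has_chr) {
        ifelse(grepl("^chr", df$chrom), df$chrom, paste0("chr", df$chrom))
      } else sub("^chr", "", df$chrom)
    }
    unknown <- !df$chrom %in% names(genome)
    if (any(unknown)) {
      stop(sum(unknown), " record(s) on chromosomes absent from the genome",
           call. = FALSE)
    }
    obs <- vapply(seq_len(nrow(df)), function(i) {
      s <- genome_seq(genome, df$chrom[i])
      substr(s, df$pos[i], df$pos[i] + nchar(df$ref[i]) - 1L)
    }, "")
    mism <- obs != df$ref
    if (any(mism)) {
      message(sum(mism), " record(s) rejected: ref allele does not match genome")
      df <- df[!mism, , drop = FALSE]
    }
  }
  df
}

#' Write mutations to TSV
#'
#' @param mutations A mutation tibble as returned by [read_mutations()].
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  readr::write_tsv(mutations[, c("chrom", "pos", "ref", "alt")], path,
                   progress = FALSE)
  invisible(mutations)
}

#' Filter mutations to those inside a mask
#'
#' A record is kept iff its 1-based anchor position `p` lies inside a mask
#' interval, i.e. `start < p <= end` for some 0-based half-open interval.
#' Indels are located by their anchor base.
#'
#' @param mutations A mutation tibble.
#' @param mask A `region_mask`.
#' @return The retained records.
#' @export
filter_by_mask <- function(mutations, mask) {
  if (nrow(mutations) == 0L) return(mutations)
  gr <- GenomicRanges::GRanges(mutations$chrom,
                               IRanges::IRanges(mutations$pos, mutations$pos))
  hits <- GenomicRanges::findOverlaps(gr, mask_to_granges(mask))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  mutations[keep, , drop = FALSE]
}
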