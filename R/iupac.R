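#' IUPAC nucleotide ambiguity codes
#'
#' The 15-letter DNA alphabet used for rate-sharing patterns: the four bases
#' plus the 11 ambiguity characters, each denoting a subset of \{A,C,G,T\}.
#' A pattern (a string over this alphabet) matches a k-mer iff at every
#' position the k-mer base belongs to the set denoted by the pattern
#' character.
#'
#' @format A named list mapping each code to its base set.
#' @export
iupac_sets <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    S = c("C", "G"), W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
}

# Fixed code order; indices into this vector are used throughout the DP.
IUPAC_CODES <- c("A", "C", "G", "T", "S", "W", "R", "Y", "K", "M",
                 "B", "D", "H", "V", "N")

# All ways to split one ambiguity code's base set into two disjoint,
# covering IUPAC-codable subsets. Order matters: it is the tie-break order
# of the optimizer.
IUPAC_TWO_PARTITIONS <- list(
  S = list(c("C", "G")),
  W = list(c("A", "T")),
  R = list(c("A", "G")),
  Y = list(c("C", "T")),
  K = list(c("G", "T")),
  M = list(c("A", "C")),
  B = list(c("C", "K"), c("G", "Y"), c("T", "S")),
  D = list(c("A", "K"), c("G", "W"), c("T", "R")),
  H = list(c("A", "Y"), c("C", "W"), c("T", "M")),
  V = list(c("A", "S"), c("C", "R"), c("G", "M")),
  N = list(c("A", "B"), c("C", "D"), c("G", "H"), c("T", "V"),
           c("R", "Y"), c("S", "W"), c("K", "M"))
)

#' Two-partitions of an IUPAC code
#'
#' Returns every way of splitting the base set of an ambiguity code into two
#' disjoint, covering subsets that are themselves IUPAC-codable. These splits
#' are the elementary refinement moves of the pattern-partition optimizer.
#'
#' @param code A single IUPAC character.
#' @return A list of length-2 character vectors (pairs of codes), in the
#'   fixed tie-break order. Single-base codes return an empty list.
#' @examples
#' two_partitions("N")
#' two_partitions("S")
#' @export
two_partitions <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!code %in% IUPAC_CODES) {
    stop("not an IUPAC code: ", code, call. = FALSE)
  }
  if (code %in% c("A", "C", "G", "T")) return(list())
  IUPAC_TWO_PARTITIONS[[code]]
}

#' Does an IUPAC pattern match each k-mer?
#'
#' @param pattern A single IUPAC pattern string.
#' @param kmers Character vector of k-mers over \{A,C,G,T\}, same length as
#'   the pattern.
#' @return Logical vector.
#' @export
pattern_matches <- function(pattern, kmers) {
  k <- nchar(pattern)
  stopifnot(all(nchar(kmers) == k))
  sets <- iupac_sets()
  pchars <- strsplit(pattern, "")[[1]]
  out <- rep(TRUE, length(kmers))
  for (i in seq_len(k)) {
    out <- out & substr(kmers, i, i) %in% sets[[pchars[i]]]
  }
  out
}

#' Expand an IUPAC pattern into the k-mers it matches
#'
#' @param pattern A single IUPAC pattern string.
#' @return Character vector of all matching k-mers (cartesian product of the
#'   per-position base sets).
#' @export
expand_pattern <- function(pattern) {
  sets <- iupac_sets()
  pchars <- strsplit(pattern, "")[[1]]
  grids <- lapply(pchars, function(ch) sets[[ch]])
  out <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  apply(out[, rev(seq_along(grids)), drop = FALSE], 1L, paste0, collapse = "")
}

#' All k-mers over \{A,C,G,T\}
#'
#' @param k k-mer length.
#' @param central Optional restriction of the central base (e.g. `c("A","C")`
#'   for strand-collapsed SNV tables; requires odd `k`).
#' @return Character vector of k-mers in lexicographic-by-position order.
#' @export
all_kmers <- function(k, central = NULL) {
  bases <- c("A", "C", "G", "T")
  sets <- rep(list(bases), k)
  if (!is.null(central)) {
    stopifnot(k %% 2L == 1L)
    sets[[(k + 1L) / 2L]] <- central
  }
  out <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(out[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
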