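# IUPAC nucleotide algebra.
#
# Every sequence handled by this package lives over the 16-letter IUPAC
# alphabet (A,C,G,T, the 11 ambiguity codes, and '-' for alignment gaps).
# Ambiguity codes are the device by which a Sanger double peak is recorded
# in a consensus sequence (e.g. an A/G double peak becomes 'R'), so the
# expand/compress pair below underpins heterozygote calling and phasing.

#' IUPAC code to base-set map
#'
#' Named list mapping each of the 15 IUPAC nucleotide symbols to the set of
#' unambiguous bases it denotes. The gap character is deliberately absent:
#' gaps are positional, not base sets.
#' @keywords internal
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set pasted -> code
.IUPAC_REV <- local({
  keys <- vapply(IUPAC_MAP, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(IUPAC_MAP), keys)
})

#' All legal sequence characters
#' @keywords internal
IUPAC_ALPHABET <- c(names(IUPAC_MAP), "-")

# bitmask encoding A=1 C=2 G=4 T=8; an ambiguity code is the OR of its bases.
# Gap encodes to 0 so that bitwAnd() with anything is 0 (never matches).
.IUPAC_BITS <- local({
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  bits <- vapply(IUPAC_MAP, function(b) sum(base_bit[b]), integer(1))
  c(bits, "-" = 0L)
})

#' Expand an IUPAC symbol to its base set
#'
#' @param code A single IUPAC nucleotide symbol (case-insensitive).
#' @param context Optional string describing where the symbol came from, used
#'   to enrich the error message on an unknown character.
#' @return Character vector of unambiguous bases, e.g. `c("A","G")` for `"R"`.
#' @examples
#' expand_iupac("R")
#' expand_iupac("N")
#' @export
expand_iupac <- function(code, context = NULL) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  bases <- IUPAC_MAP[[code]]
  if (is.null(bases)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop("unknown IUPAC symbol '", code, "'", where, call. = FALSE)
  }
  bases
}

#' Compress a base set to its canonical IUPAC symbol
#'
#' Inverse of [expand_iupac()]: `expand_iupac(compress_iupac(s))` recovers `s`
#' for every non-empty subset of \{A,C,G,T\}.
#'
#' @param bases Character vector, a non-empty subset of A/C/G/T (duplicates
#'   tolerated).
#' @return Single IUPAC symbol.
#' @examples
#' compress_iupac(c("A", "G"))   # "R"
#' compress_iupac("C")           # identity on single bases
#' @export
compress_iupac <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("base set must be drawn from {A,C,G,T}, got: ",
         paste(bases, collapse = ","), call. = FALSE)
  }
  unname(.IUPAC_REV[[paste(sort(bases), collapse = "")]])
}

#' Encode a sequence string as an IUPAC bitmask vector
#'
#' A=1, C=2, G=4, T=8; ambiguity codes OR their bases; gaps encode to 0.
#' Two symbols are compatible (their base sets intersect) iff the bitwise AND
#' of their masks is non-zero — the primitive behind degenerate primer
#' matching and ambiguity-aware p-distances.
#'
#' @param seq Single sequence string.
#' @param context Optional provenance string for error messages.
#' @return Integer vector, one mask per position.
#' @keywords internal
iupac_bits <- function(seq, context = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bits <- .IUPAC_BITS[chars]
  bad <- which(is.na(bits) | !(chars %in% IUPAC_ALPHABET))
  if (length(bad)) {
    where <- if (is.null(context)) "" else paste0(" in ", context)
    stop("non-IUPAC character '", chars[bad[1]], "' at position ", bad[1],
         where, call. = FALSE)
  }
  unname(bits)
}

#' Validate that a string is a legal IUPAC sequence
#' @keywords internal
check_iupac_sequence <- function(seq, context = NULL) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be a single non-empty string",
         if (!is.null(context)) paste0(" (", context, ")"), call. = FALSE)
  }
  invisible(iupac_bits(seq, context = context))
}

#' Reverse-complement a sequence, honouring ambiguity codes
#'
#' @param seq Sequence string over the IUPAC alphabet (no gaps).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Per-position IUPAC union of two equal-length sequences
#'
#' Used by the phase-merge inversion check: merging a phased haplotype pair
#' back together must reproduce the ambiguous consensus at panel positions.
#'
#' @param a,b Equal-length gap-free sequence strings.
#' @return Sequence string where each position holds the IUPAC code of the
#'   union of the two input base sets.
#' @export
iupac_union <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences differ in length", call. = FALSE)
  paste(mapply(function(x, y) {
    compress_iupac(union(expand_iupac(x), expand_iupac(y)))
  }, ca, cb, USE.NAMES = FALSE), collapse = "")
}
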