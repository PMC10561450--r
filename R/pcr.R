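# In silico multiplex PCR.
#
# The assay carries one primer pair per species variant of the TROSPA intron;
# products of distinct sizes make the species call readable on a gel, and a
# two-band lane flags a hybrid carrying one allele of each species.
#
# Matching semantics: a primer binds where it aligns with at most
# `max_mismatches` incompatible positions AND its 3'-terminal `three_prime_anchor`
# bases are all compatible (polymerase extension is intolerant of 3' mismatches).
# Degenerate primer bases match any base in their IUPAC expansion.
#
# All coordinates are 1-based and closed ([start, end] spans the footprint on
# the plus strand), the convention of IRanges and of every report this package
# writes.

#' Construct a primer
#'
#' @param name Primer name.
#' @param sequence 5'->3' sequence over A/C/G/T plus IUPAC degeneracies;
#'   gaps are illegal; minimum length 15.
#' @param max_mismatches Maximum tolerated incompatible positions outside the
#'   3' anchor (default 2).
#' @param three_prime_anchor Number of 3'-terminal bases that must match with
#'   zero mismatches (default 5).
#' @return A `primer` object.
#' @export
primer <- function(name, sequence, max_mismatches = 2L, three_prime_anchor = 5L) {
  sequence <- toupper(sequence)
  check_iupac_sequence(sequence, context = paste("primer", name))
  if (grepl("-", sequence, fixed = TRUE)) {
    stop("primer '", name, "' contains a gap", call. = FALSE)
  }
  if (nchar(sequence) < 15L) {
    stop("primer '", name, "' shorter than 15 nt", call. = FALSE)
  }
  if (three_prime_anchor > nchar(sequence)) {
    stop("anchor longer than primer '", name, "'", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 max_mismatches = as.integer(max_mismatches),
                 three_prime_anchor = as.integer(three_prime_anchor)),
            class = "primer")
}

#' Construct a two-pair multiplex assay
#'
#' @param fwd_A,rev_A Primer pair for species A with expected product size
#'   `size_A` (bp); likewise `fwd_B`/`rev_B`/`size_B` for species B.
#' @param size_A,size_B Expected product sizes in bp.
#' @param size_tolerance Band-size tolerance in bp (gel resolution proxy,
#'   default 10). The two expected sizes must be distinguishable:
#'   `|size_A - size_B| > 2 * size_tolerance`.
#' @param max_product Longest product considered (default 2000 bp).
#' @return A `multiplex_assay` object.
#' @export
multiplex_assay <- function(fwd_A, rev_A, size_A, fwd_B, rev_B, size_B,
                            size_tolerance = 10L, max_product = 2000L) {
  stopifnot(inherits(fwd_A, "primer"), inherits(rev_A, "primer"),
            inherits(fwd_B, "primer"), inherits(rev_B, "primer"),
            size_A > 0, size_B > 0)
  if (abs(size_A - size_B) <= 2L * size_tolerance) {
    stop("expected product sizes not distinguishable at the given tolerance",
         call. = FALSE)
  }
  structure(list(fwd_A = fwd_A, rev_A = rev_A, size_A = as.integer(size_A),
                 fwd_B = fwd_B, rev_B = rev_B, size_B = as.integer(size_B),
                 size_tolerance = as.integer(size_tolerance),
                 max_product = as.integer(max_product)),
            class = "multiplex_assay")
}

#' Read a primer panel TSV and build the multiplex assay
#'
#' Expects columns name, sequence, role (fwd_A/rev_A/fwd_B/rev_B),
#' expected_size, and optionally annealing_c (stored, never used
#' computationally).
#'
#' @param path Panel TSV path.
#' @param ... Passed to [multiplex_assay()] (e.g. `size_tolerance`).
#' @return A `multiplex_assay`.
#' @export
read_primer_panel <- function(path, ...) {
  tab <- read_tsv(path)
  need <- c("name", "sequence", "role", "expected_size")
  if (!all(need %in% names(tab))) {
    stop("primer panel must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  get <- function(role) {
    row <- tab[tab$role == role, , drop = FALSE]
    if (nrow(row) != 1L) stop("panel needs exactly one '", role, "' primer",
                              call. = FALSE)
    row
  }
  fa <- get("fwd_A"); ra <- get("rev_A"); fb <- get("fwd_B"); rb <- get("rev_B")
  multiplex_assay(
    fwd_A = primer(fa$name, fa$sequence), rev_A = primer(ra$name, ra$sequence),
    size_A = fa$expected_size,
    fwd_B = primer(fb$name, fb$sequence), rev_B = primer(rb$name, rb$sequence),
    size_B = fb$expected_size, ...)
}

# vectorised mismatch profile of `pbits` against every window of `tbits`;
# returns an integer matrix with one row per window start and per-position
# compatibility handled via bitmask intersection.
.window_mismatches <- function(tbits, pbits, anchor_idx) {
  n <- length(tbits); m <- length(pbits)
  if (m > n) return(NULL)
  starts <- seq_len(n - m + 1L)
  mm <- integer(length(starts))
  anchor_bad <- logical(length(starts))
  for (j in seq_len(m)) {
    incompatible <- bitwAnd(pbits[j], tbits[starts + j - 1L]) == 0L
    mm <- mm + incompatible
    if (j %in% anchor_idx) anchor_bad <- anchor_bad | incompatible
  }
  list(starts = starts, mismatches = mm, anchor_bad = anchor_bad)
}

#' Find primer binding sites on both strands of a template
#'
#' Scans the template (gap-free; gaps are stripped with a warning) for windows
#' where the primer matches with at most `primer$max_mismatches` incompatible
#' positions and an exactly matching 3' anchor. On the minus strand the
#' reverse-complemented primer is scanned, so a site's coordinates are always
#' 1-based closed on the plus strand.
#'
#' @param template Sequence string or one-row `marker_set`.
#' @param primer A [primer()].
#' @return data.frame with columns template_id, strand ("+"/"-"), start, end,
#'   mismatches, sorted by start. Empty (zero rows) when nothing binds or the
#'   primer is longer than the template.
#' @export
find_primer_sites <- function(template, primer) {
  if (inherits(template, "marker_set") || is.data.frame(template)) {
    template_id <- template$sample_id[1]
    seq <- template$sequence[1]
  } else {
    template_id <- attr(template, "sample_id") %||% "template"
    seq <- template
  }
  seq <- toupper(seq)
  if (grepl("-", seq, fixed = TRUE)) {
    warning("gaps stripped from template before primer scan", call. = FALSE)
    seq <- gsub("-", "", seq, fixed = TRUE)
  }
  tbits <- iupac_bits(seq, context = template_id)
  m <- nchar(primer$sequence)
  empty <- data.frame(template_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (m > length(tbits)) return(empty)

  hits <- list()
  # plus strand: 3' anchor is the rightmost `anchor` primer bases
  pb <- iupac_bits(primer$sequence)
  anchor_idx <- seq.int(m - primer$three_prime_anchor + 1L, m)
  sc <- .window_mismatches(tbits, pb, anchor_idx)
  keep <- !sc$anchor_bad & sc$mismatches <= primer$max_mismatches
  if (any(keep)) {
    hits[["+"]] <- data.frame(template_id = template_id, strand = "+",
                              start = sc$starts[keep],
                              end = sc$starts[keep] + m - 1L,
                              mismatches = sc$mismatches[keep],
                              stringsAsFactors = FALSE)
  }
  # minus strand: scan revcomp(primer); its 3' end sits at the LEFT edge
  prc <- iupac_bits(revcomp(primer$sequence))
  anchor_idx_rc <- seq_len(primer$three_prime_anchor)
  sc <- .window_mismatches(tbits, prc, anchor_idx_rc)
  keep <- !sc$anchor_bad & sc$mismatches <= primer$max_mismatches
  if (any(keep)) {
    hits[["-"]] <- data.frame(template_id = template_id, strand = "-",
                              start = sc$starts[keep],
                              end = sc$starts[keep] + m - 1L,
                              mismatches = sc$mismatches[keep],
                              stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict amplicons from a primer set on one template
#'
#' Every pairing of a forward-primer site on the plus strand with a
#' reverse-primer site on the minus strand, with the forward 5' end upstream
#' of the reverse 5' end and a product no longer than `max_product`, yields
#' one amplicon. Product length is counted 5'-to-5' inclusive of both primer
#' footprints, the convention in which multiplex product sizes are reported.
#'
#' @param template Sequence string or one-row `marker_set`.
#' @param forward,reverse [primer()] objects.
#' @param max_product Maximum product size in bp (default 2000).
#' @return data.frame with columns forward_primer, reverse_primer, length,
#'   template_id, start, end (1-based closed product span).
#' @export
predict_amplicons <- function(template, forward, reverse, max_product = 2000L) {
  fsites <- find_primer_sites(template, forward)
  rsites <- find_primer_sites(template, reverse)
  fsites <- fsites[fsites$strand == "+", , drop = FALSE]
  rsites <- rsites[rsites$strand == "-", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fsites))) {
    for (j in seq_len(nrow(rsites))) {
      len <- rsites$end[j] - fsites$start[i] + 1L
      if (len > 0L && len <= max_product &&
          fsites$start[i] < rsites$end[j]) {
        out[[length(out) + 1L]] <- data.frame(
          forward_primer = forward$name, reverse_primer = reverse$name,
          length = len, template_id = fsites$template_id[i],
          start = fsites$start[i], end = rsites$end[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(forward_primer = character(), reverse_primer = character(),
                      length = integer(), template_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.pair_band <- function(templates, fwd, rev, expected, tolerance, max_product) {
  for (tpl in templates) {
    amps <- predict_amplicons(tpl, fwd, rev, max_product = max_product)
    if (nrow(amps) && any(abs(amps$length - expected) <= tolerance)) return(TRUE)
  }
  FALSE
}

#' Run the multiplex gel classification on a diploid template set
#'
#' @param templates Character vector of one or two TROSPA allele sequences
#'   (the diploid locus).
#' @param assay A [multiplex_assay()].
#' @return A `gel_pattern` list with elements `bands` (subset of
#'   c("A","B")) and `verdict` (SPECIES_A / SPECIES_B / HYBRID / NONE).
#' @export
multiplex_gel <- function(templates, assay) {
  stopifnot(length(templates) %in% c(1L, 2L))
  a <- .pair_band(templates, assay$fwd_A, assay$rev_A, assay$size_A,
                  assay$size_tolerance, assay$max_product)
  b <- .pair_band(templates, assay$fwd_B, assay$rev_B, assay$size_B,
                  assay$size_tolerance, assay$max_product)
  bands <- c(if (a) "A", if (b) "B")
  verdict <- if (a && b) "HYBRID" else if (a) "SPECIES_A" else if (b) "SPECIES_B" else "NONE"
  structure(list(bands = bands, verdict = verdict), class = "gel_pattern")
}

#' @export
print.gel_pattern <- function(x, ...) {
  cat("<gel_pattern> bands: {", paste(x$bands, collapse = ","), "} verdict: ",
      x$verdict, "\n", sep = "")
  invisible(x)
}

#' The packaged TROSPA multiplex assay
#'
#' Loads the four-primer TROSPA panel shipped with the package (species-A
#' product 362 bp, species-B product 233 bp) as a [multiplex_assay()].
#'
#' @param ... Passed to [multiplex_assay()].
#' @return A `multiplex_assay`.
#' @export
trospa_assay <- function(...) {
  read_primer_panel(system.file("extdata", "trospa_multiplex.tsv",
                                package = "tickhybrid", mustWork = TRUE), ...)
}
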