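# TROSPA sequence-level diagnostics.
#
# Four stages: (1) discovery of fixed inter-species SNP panels from labelled
# alignments; (2) both-strand double-peak detection on chromatogram-like
# traces, with the two Geneious-style thresholds exposed; (3) species/hybrid
# calling of a sample against the panel; (4) phasing of a hybrid consensus
# into its two species haplotypes, the in-silico analogue of cloning the PCR
# product.

.as_char_matrix <- function(seqs) {
  if (inherits(seqs, "marker_set") || is.data.frame(seqs)) seqs <- seqs$sequence
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Discover fixed diagnostic SNPs between two labelled alignments
#'
#' A column is diagnostic when every species-A sequence carries one fixed
#' unambiguous base, every species-B sequence carries a different fixed
#' unambiguous base, and no sequence carries a gap or ambiguity code there.
#'
#' @param alignment_A,alignment_B `marker_set`s (or character vectors) of
#'   pre-aligned, equal-length sequences, one per species.
#' @param reference_id Name the positions are reported against; defaults to
#'   the first species-A sequence id.
#' @return A `diagnostic_table` data.frame (reference_id, position, allele_A,
#'   allele_B), positions 1-based and strictly increasing. Zero rows when no
#'   column is fixed-different.
#' @export
find_diagnostic_snps <- function(alignment_A, alignment_B,
                                 reference_id = NULL) {
  get_ids <- function(x) if (is.data.frame(x)) x$sample_id else NULL
  if (!length(alignment_A) || (is.data.frame(alignment_A) && !nrow(alignment_A)) ||
      !length(alignment_B) || (is.data.frame(alignment_B) && !nrow(alignment_B))) {
    stop("empty alignment group", call. = FALSE)
  }
  A <- .as_char_matrix(alignment_A)
  B <- .as_char_matrix(alignment_B)
  if (ncol(A) != ncol(B)) {
    stop("species alignments have different lengths", call. = FALSE)
  }
  if (is.null(reference_id)) {
    reference_id <- get_ids(alignment_A)[1] %||% "alignment_A_1"
  }
  plain <- c("A", "C", "G", "T")
  a_fixed <- colSums(A != A[rep(1L, nrow(A)), , drop = FALSE]) == 0L
  b_fixed <- colSums(B != B[rep(1L, nrow(B)), , drop = FALSE]) == 0L
  clean <- A[1, ] %in% plain & B[1, ] %in% plain &
    apply(A, 2, function(col) all(col %in% plain)) &
    apply(B, 2, function(col) all(col %in% plain))
  hit <- which(a_fixed & b_fixed & clean & A[1, ] != B[1, ])
  tab <- data.frame(reference_id = rep(reference_id, length(hit)),
                    position = hit,
                    allele_A = A[1, hit],
                    allele_B = B[1, hit],
                    stringsAsFactors = FALSE)
  class(tab) <- c("diagnostic_table", "data.frame")
  tab
}

#' Peak-calling thresholds
#'
#' @param similarity_threshold Minimum secondary/primary channel height ratio
#'   for a double peak (default 0.30; the comparison is `>=`).
#' @param height_threshold Minimum primary height as a fraction of the local
#'   running maximum signal (default 0.50).
#' @param require_both_strands Report a position only when both strands show
#'   the double peak with the same base pair (default TRUE).
#' @param local_window Width in positions of the running-maximum window used
#'   for the height threshold (default 21, centred).
#' @return A `peak_call_settings` list.
#' @export
peak_call_settings <- function(similarity_threshold = 0.30,
                               height_threshold = 0.50,
                               require_both_strands = TRUE,
                               local_window = 21L) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1,
            height_threshold > 0, height_threshold <= 1)
  structure(list(similarity_threshold = similarity_threshold,
                 height_threshold = height_threshold,
                 require_both_strands = require_both_strands,
                 local_window = as.integer(local_window)),
            class = "peak_call_settings")
}

.rolling_max <- function(x, w) {
  half <- w %/% 2L
  out <- x
  for (d in seq_len(half)) {
    n <- length(x)
    out <- pmax(out, c(x[-seq_len(d)], rep(-Inf, d)),
                c(rep(-Inf, d), x[seq_len(n - d)]))
  }
  out
}

.strand_calls <- function(h, settings) {
  n <- nrow(h)
  ord1 <- max.col(h, ties.method = "first")
  prim_h <- h[cbind(seq_len(n), ord1)]
  h2 <- h
  h2[cbind(seq_len(n), ord1)] <- -Inf
  ord2 <- max.col(h2, ties.method = "first")
  sec_h <- h[cbind(seq_len(n), ord2)]
  zero <- prim_h <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-signal position(s) skipped", call. = FALSE)
  }
  local_max <- .rolling_max(prim_h, settings$local_window)
  het <- !zero &
    sec_h >= settings$similarity_threshold * prim_h &
    prim_h >= settings$height_threshold * local_max
  bases <- colnames(h)
  list(het = het, primary = bases[ord1], secondary = bases[ord2], zero = zero)
}

#' Detect both-strand double peaks in a trace
#'
#' A position is reported when, on each required strand, the secondary channel
#' reaches at least `similarity_threshold` of the primary channel and the
#' primary reaches at least `height_threshold` of the local running-maximum
#' signal. Reverse-strand base calls are complemented to plus-strand
#' orientation; positions where the two strands disagree on the base pair are
#' dropped with a note.
#'
#' @param trace A `chromatogram`.
#' @param settings A [peak_call_settings()].
#' @return data.frame with columns position, base1, base2 (alphabetical order
#'   of the pair on the plus strand) and code (the IUPAC symbol of the pair),
#'   sorted by position.
#' @export
detect_double_peaks <- function(trace, settings = peak_call_settings()) {
  f <- .strand_calls(trace$forward, settings)
  r <- .strand_calls(trace$reverse, settings)
  r_primary <- unname(.COMPLEMENT[r$primary])
  r_secondary <- unname(.COMPLEMENT[r$secondary])
  pair_key <- function(x, y) {
    paste(pmin(x, y), pmax(x, y))
  }
  f_pair <- pair_key(f$primary, f$secondary)
  r_pair <- pair_key(r_primary, r_secondary)
  if (settings$require_both_strands) {
    cand <- which(f$het & r$het)
    agree <- f_pair[cand] == r_pair[cand]
    if (any(!agree)) {
      message(sum(!agree), " double-peak position(s) dropped: strands disagree ",
              "on the base pair")
    }
    pos <- cand[agree]
    b1 <- pmin(f$primary[pos], f$secondary[pos])
    b2 <- pmax(f$primary[pos], f$secondary[pos])
  } else {
    pos <- which(f$het | r$het)
    use_f <- f$het[pos]
    b1 <- ifelse(use_f, pmin(f$primary[pos], f$secondary[pos]),
                 pmin(r_primary[pos], r_secondary[pos]))
    b2 <- ifelse(use_f, pmax(f$primary[pos], f$secondary[pos]),
                 pmax(r_primary[pos], r_secondary[pos]))
  }
  out <- data.frame(position = pos, base1 = b1, base2 = b2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  out$code <- vapply(seq_len(nrow(out)), function(i) {
    compress_iupac(c(out$base1[i], out$base2[i]))
  }, "")
  rownames(out) <- NULL
  out
}

#' Call a consensus sequence with IUPAC ambiguities from a trace
#'
#' The forward-strand primary base everywhere, except detected double-peak
#' positions, which receive the IUPAC code of the base pair.
#'
#' @inheritParams detect_double_peaks
#' @return Consensus sequence string (length = trace length).
#' @export
consensus_with_ambiguities <- function(trace, settings = peak_call_settings()) {
  f <- .strand_calls(trace$forward, settings)
  chars <- f$primary
  peaks <- detect_double_peaks(trace, settings)
  if (nrow(peaks)) chars[peaks$position] <- peaks$code
  paste(chars, collapse = "")
}

# double peaks encoded in a consensus: positions whose IUPAC code expands to
# exactly two bases (N is treated as missing data, not a double peak)
.consensus_peaks <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  sets <- IUPAC_MAP[chars]
  two <- which(vapply(sets, length, 1L) == 2L)
  data.frame(position = two,
             base1 = vapply(sets[two], function(s) sort(s)[1], ""),
             base2 = vapply(sets[two], function(s) sort(s)[2], ""),
             code = chars[two],
             stringsAsFactors = FALSE)
}

#' Classify a sample as species A/B, hybrid, or indeterminate
#'
#' A sample is HYBRID when at least `hybrid_min_fraction` of the panel
#' positions show a double peak and every on-panel double peak carries exactly
#' the two species alleles. Otherwise the homozygous panel positions vote for
#' species A or B by majority; ties, panel coverage below 50%, or a total
#' double-peak count above `max_noise_het` (without a hybrid signature) give
#' INDETERMINATE.
#'
#' @param x A `chromatogram` or a consensus sequence string containing IUPAC
#'   ambiguity codes.
#' @param table A `diagnostic_table`.
#' @param settings [peak_call_settings()], used when `x` is a trace.
#' @param hybrid_min_fraction Minimum matched fraction of the panel for a
#'   hybrid call (default 0.85; set to 1.0 for strict replication).
#' @param max_noise_het Largest double-peak count still attributed to noise
#'   in a non-hybrid (default 15).
#' @return A `trospa_call` list: sample_id, double_peak_positions,
#'   n_diagnostic_het, n_offtarget_het, matched_fraction, verdict
#'   (RIC/INO/HYBRID/INDETERMINATE), homozygous_species_votes.
#' @export
call_sample <- function(x, table, settings = peak_call_settings(),
                        hybrid_min_fraction = 0.85, max_noise_het = 15L) {
  if (!nrow(table)) stop("empty diagnostic table", call. = FALSE)
  if (inherits(x, "chromatogram")) {
    sample_id <- x$sample_id
    peaks <- detect_double_peaks(x, settings)
    consensus <- consensus_with_ambiguities(x, settings)
  } else {
    sample_id <- attr(x, "sample_id") %||% "sample"
    consensus <- toupper(x)
    peaks <- .consensus_peaks(consensus)
  }
  if (nchar(consensus) < max(table$position)) {
    stop("consensus shorter than the largest panel position (coverage error)",
         call. = FALSE)
  }
  chars <- strsplit(consensus, "")[[1]]
  on_panel <- peaks$position %in% table$position
  n_diag <- sum(on_panel)
  n_off <- sum(!on_panel)
  matched_fraction <- n_diag / nrow(table)

  # do the on-panel double peaks carry the two species alleles?
  pairs_ok <- TRUE
  if (n_diag > 0) {
    pk <- peaks[on_panel, , drop = FALSE]
    rows <- match(pk$position, table$position)
    want1 <- pmin(table$allele_A[rows], table$allele_B[rows])
    want2 <- pmax(table$allele_A[rows], table$allele_B[rows])
    pairs_ok <- all(pk$base1 == want1 & pk$base2 == want2)
  }

  hom <- chars[table$position]
  votes_A <- sum(hom == table$allele_A)
  votes_B <- sum(hom == table$allele_B)
  coverage <- (votes_A + votes_B + n_diag) / nrow(table)

  verdict <- if (matched_fraction >= hybrid_min_fraction && pairs_ok) {
    "HYBRID"
  } else if (nrow(peaks) > max_noise_het) {
    "INDETERMINATE"
  } else if (coverage < 0.5 || votes_A == votes_B) {
    "INDETERMINATE"
  } else if (votes_A > votes_B) "RIC" else "INO"

  structure(list(sample_id = sample_id,
                 double_peak_positions = peaks$position,
                 n_diagnostic_het = n_diag, n_offtarget_het = n_off,
                 matched_fraction = matched_fraction,
                 verdict = verdict,
                 homozygous_species_votes = c(n_A = votes_A, n_B = votes_B)),
            class = "trospa_call")
}

#' @export
print.trospa_call <- function(x, ...) {
  cat(sprintf("<trospa_call> %s: %s (%d double peaks, %d on panel, matched %.2f)\n",
              x$sample_id, x$verdict,
              length(x$double_peak_positions), x$n_diagnostic_het,
              x$matched_fraction))
  invisible(x)
}

#' Phase a hybrid consensus into its two species haplotypes
#'
#' The in-silico analogue of cloning: at every heterozygous panel position,
#' haplotype 1 receives the species-A allele and haplotype 2 the species-B
#' allele. Panel positions observed homozygous keep their observed base in
#' both haplotypes. Heterozygous positions off the panel cannot be phased
#' without linkage information; both haplotypes receive the alphabetically
#' first base of the pair and the position is flagged.
#'
#' @param consensus Consensus sequence string with IUPAC ambiguity codes.
#' @param table A `diagnostic_table`.
#' @param sample_id Used to derive the clone-style haplotype ids
#'   (`<id>_cl1`, `<id>_cl2`).
#' @param min_fraction Minimum fraction of panel positions that must be
#'   heterozygous with the species base pair (default 0.85).
#' @return A `haplotype_pair` list: haplotype_1, haplotype_2 (strings),
#'   ids, species_assignment c("A","B"), unphased_positions (off-panel
#'   heterozygous positions).
#' @export
phase_hybrid <- function(consensus, table, sample_id = "hybrid",
                         min_fraction = 0.85) {
  if (!nrow(table)) stop("empty diagnostic table", call. = FALSE)
  consensus <- toupper(consensus)
  peaks <- .consensus_peaks(consensus)
  if (!nrow(peaks)) {
    stop("consensus carries no ambiguity codes; nothing to phase", call. = FALSE)
  }
  chars <- strsplit(consensus, "")[[1]]
  if (length(chars) < max(table$position)) {
    stop("consensus shorter than the largest panel position", call. = FALSE)
  }
  on_panel <- peaks[peaks$position %in% table$position, , drop = FALSE]
  rows <- match(on_panel$position, table$position)
  want1 <- pmin(table$allele_A[rows], table$allele_B[rows])
  want2 <- pmax(table$allele_A[rows], table$allele_B[rows])
  bad <- which(on_panel$base1 != want1 | on_panel$base2 != want2)
  if (length(bad)) {
    stop("species-inconsistent base pair at panel position ",
         on_panel$position[bad[1]], call. = FALSE)
  }
  if (nrow(on_panel) / nrow(table) < min_fraction) {
    stop("consensus heterozygous at only ", nrow(on_panel), "/", nrow(table),
         " panel positions; below the hybrid threshold", call. = FALSE)
  }
  h1 <- h2 <- chars
  rows <- match(on_panel$position, table$position)
  h1[on_panel$position] <- table$allele_A[rows]
  h2[on_panel$position] <- table$allele_B[rows]
  off <- peaks[!peaks$position %in% table$position, , drop = FALSE]
  if (nrow(off)) {
    h1[off$position] <- off$base1
    h2[off$position] <- off$base1
  }
  structure(list(haplotype_1 = paste(h1, collapse = ""),
                 haplotype_2 = paste(h2, collapse = ""),
                 ids = paste0(sample_id, c("_cl1", "_cl2")),
                 species_assignment = c("A", "B"),
                 unphased_positions = off$position),
            class = "haplotype_pair")
}

#' @export
print.haplotype_pair <- function(x, ...) {
  cat(sprintf("<haplotype_pair> %s / %s (%d unphased off-panel site(s))\n",
              x$ids[1], x$ids[2], length(x$unphased_positions)))
  invisible(x)
}
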