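# Haplotype dereplication, motif typing, identity statistics, and p-distance
# nearest-reference assignment (a lightweight stand-in for tree placement).

#' Collapse aligned sequences into unique haplotype records
#'
#' Exact-string grouping after uppercasing; gap columns are kept as-is.
#' Records are sorted by descending count, ties broken by first appearance.
#'
#' @param seqs A `marker_set` (or character vector) of equal-length sequences.
#' @return data.frame (class `haplotype_records`) with columns haplotype_id,
#'   sequence, count, members (comma-joined sample ids), origins
#'   (comma-joined origins represented).
#' @export
dereplicate <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- marker_set(sprintf("seq%03d", seq_along(seqs)), seqs,
                       marker = "S16", origin = "OTHER")
  }
  lens <- nchar(seqs$sequence)
  if (nrow(seqs) && length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  up <- toupper(seqs$sequence)
  first_seen <- !duplicated(up)
  key <- match(up, up[first_seen])
  grp <- split(seq_len(nrow(seqs)), key)
  ord_first <- vapply(grp, min, 1L)
  counts <- lengths(grp)
  o <- order(-counts, ord_first)
  grp <- grp[o]
  out <- data.frame(
    haplotype_id = sprintf("hap%02d", seq_along(grp)),
    sequence = vapply(grp, function(ix) up[ix[1]], ""),
    count = unname(lengths(grp)),
    members = vapply(grp, function(ix) paste(seqs$sample_id[ix], collapse = ","), ""),
    origins = vapply(grp, function(ix)
      paste(sort(unique(seqs$origin[ix])), collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("haplotype_records", "data.frame")
  out
}

#' Type a haplotype by the bases at two motif positions
#'
#' @param seq Sequence string.
#' @param motif_positions Ordered pair of 1-based positions.
#' @return "AG", "CT", "AT" when the concatenated bases form one of the named
#'   states; otherwise "OTHER" (including, with a warning, any ambiguity code
#'   or gap at a motif position).
#' @export
type_haplotype <- function(seq, motif_positions) {
  stopifnot(length(motif_positions) == 2L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (max(motif_positions) > length(chars)) {
    stop("sequence does not cover the motif positions", call. = FALSE)
  }
  b <- chars[motif_positions]
  if (!all(b %in% c("A", "C", "G", "T"))) {
    warning("ambiguity code or gap at a motif position; labelling OTHER",
            call. = FALSE)
    return("OTHER")
  }
  lab <- paste(b, collapse = "")
  if (lab %in% c("AG", "CT", "AT")) lab else "OTHER"
}

# percent identity of two aligned char vectors: positions where either side
# is a gap or N are excluded from numerator and denominator
.pid <- function(x, y) {
  usable <- !(x %in% c("-", "N")) & !(y %in% c("-", "N"))
  n <- sum(usable)
  if (n == 0L) return(NA_real_)
  100 * sum(x[usable] == y[usable]) / n
}

#' Pairwise identity matrix of aligned sequences
#'
#' @param seqs Character vector (or `marker_set`) of equal-length sequences.
#' @return Symmetric percent-identity matrix with 100 on the diagonal.
#' @export
pairwise_identity_matrix <- function(seqs) {
  M <- .as_char_matrix(seqs)
  n <- nrow(M)
  out <- matrix(100, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        out[i, j] <- out[j, i] <- .pid(M[i, ], M[j, ])
      }
    }
  }
  out
}

#' Identity statistics over haplotype records
#'
#' @param records A `haplotype_records` data.frame (or anything
#'   [pairwise_identity_matrix()] accepts).
#' @return List with `matrix` and `range` (min/max percent identity over
#'   distinct pairs). With fewer than two records both are empty.
#' @export
pairwise_identity <- function(records) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  if (length(seqs) < 2L) {
    return(list(matrix = matrix(numeric(0), 0, 0), range = numeric(0)))
  }
  m <- pairwise_identity_matrix(seqs)
  off <- m[upper.tri(m)]
  list(matrix = m, range = c(min = min(off), max = max(off)))
}

#' Build a labelled reference panel
#'
#' @param seqs A `marker_set` of aligned reference sequences.
#' @param labels Character vector of species labels, one per sequence.
#' @return A `reference_panel` list.
#' @export
reference_panel <- function(seqs, labels) {
  stopifnot(nrow(seqs) == length(labels), nrow(seqs) >= 1L)
  if (length(unique(nchar(seqs$sequence))) != 1L) {
    stop("panel references are not aligned", call. = FALSE)
  }
  structure(list(seqs = seqs, labels = as.character(labels)),
            class = "reference_panel")
}

# ambiguity-aware p-distance: a position counts as a match when the two
# IUPAC base sets intersect; gap columns are excluded pairwise
.pdist <- function(qbits, rbits) {
  usable <- qbits > 0L & rbits > 0L
  n <- sum(usable)
  if (n == 0L) return(NA_real_)
  sum(bitwAnd(qbits[usable], rbits[usable]) == 0L) / n
}

#' Assign a query to the nearest reference species by mean p-distance
#'
#' Computes the mean p-distance from the query to each species' references
#' (IUPAC codes match when base sets intersect; gaps excluded pairwise) and
#' returns the closest species. The margin — second-best minus best mean
#' distance — measures how separated the assignment is; ties give UNASSIGNED.
#'
#' @param query Sequence string, aligned to the panel length.
#' @param panel A [reference_panel()].
#' @return List: label, p_distance (best mean), margin.
#' @export
assign_by_nearest_reference <- function(query, panel) {
  qbits <- iupac_bits(toupper(query))
  refs <- panel$seqs$sequence
  if (nchar(query) != nchar(refs[1])) {
    stop("query length does not match the panel alignment", call. = FALSE)
  }
  d <- vapply(refs, function(r) .pdist(qbits, iupac_bits(r)), numeric(1))
  means <- tapply(d, panel$labels, mean)
  o <- order(means)
  best <- means[o[1]]
  second <- if (length(means) > 1L) means[o[2]] else NA_real_
  label <- names(means)[o[1]]
  if (!is.na(second) && second == best) label <- "UNASSIGNED"
  list(label = label, p_distance = unname(best),
       margin = unname(second - best))
}

#' Reference panel of a marker pool pair
#'
#' Convenience: labels every species-A allele "A" and species-B allele "B".
#' @param pool_pair List with `ric` and `ino` `marker_set`s (e.g. from
#'   [generate_marker_pool()]) or an allele-pool pair from
#'   [generate_allele_pools()].
#' @return A `reference_panel`.
#' @export
pool_reference_panel <- function(pool_pair) {
  if (inherits(pool_pair$ric, "allele_pool")) {
    a <- pool_alignment(pool_pair$ric)
    b <- pool_alignment(pool_pair$ino)
  } else {
    a <- pool_pair$ric
    b <- pool_pair$ino
  }
  seqs <- rbind(a, b)
  class(seqs) <- c("marker_set", "data.frame")
  reference_panel(seqs, c(rep("A", nrow(a)), rep("B", nrow(b))))
}
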