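# Synthetic TROSPA allele pools.
#
# The generator emulates the structure the analysis assumes: two species
# allele pools over a 670 bp intron region that differ at exactly a fixed
# panel of diagnostic positions (default 23), with within-species
# polymorphism confined to non-diagnostic positions.
#
# When a multiplex assay is supplied, the four primer footprints are embedded
# in the region and four of the diagnostic positions are placed inside the
# 3' anchor of the opposite species' primers. One panel SNP in an anchor is
# what makes each primer pair species-specific, so the same 23-position panel
# simultaneously drives the gel assay and the sequence-level diagnosis —
# mirroring how the real assay's primers sit on inter-species differences in
# the intron.

.assay_geometry <- function(assay, region_length) {
  lfA <- nchar(assay$fwd_A$sequence); lrA <- nchar(assay$rev_A$sequence)
  lfB <- nchar(assay$fwd_B$sequence); lrB <- nchar(assay$rev_B$sequence)
  fA_start <- 51L
  rA_end <- fA_start + assay$size_A - 1L
  fB_start <- 121L
  rB_end <- fB_start + assay$size_B - 1L
  fp <- list(
    fwd_A = c(fA_start, fA_start + lfA - 1L),
    fwd_B = c(fB_start, fB_start + lfB - 1L),
    rev_B = c(rB_end - lrB + 1L, rB_end),
    rev_A = c(rA_end - lrA + 1L, rA_end))
  if (rA_end + 10L > region_length) {
    stop("region_length too short to embed the assay (need >= ",
         rA_end + 10L, ")", call. = FALSE)
  }
  spans <- do.call(rbind, fp)
  if (any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
    stop("assay geometry: primer footprints overlap", call. = FALSE)
  }
  # anchor = 5 bases at the primer 3' end, mapped to plus-strand coordinates:
  # rightmost for forward primers, leftmost for reverse primers
  anchors <- list(
    fwd_A = seq(fp$fwd_A[2] - assay$fwd_A$three_prime_anchor + 1L, fp$fwd_A[2]),
    fwd_B = seq(fp$fwd_B[2] - assay$fwd_B$three_prime_anchor + 1L, fp$fwd_B[2]),
    rev_B = seq(fp$rev_B[1], fp$rev_B[1] + assay$rev_B$three_prime_anchor - 1L),
    rev_A = seq(fp$rev_A[1], fp$rev_A[1] + assay$rev_A$three_prime_anchor - 1L))
  list(footprints = fp, anchors = anchors)
}

.mutate_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1L)
}

.set_chars <- function(chars, positions, values) {
  chars[positions] <- values
  chars
}

.pool_templates_clean <- function(ric_seqs, ino_seqs, assay) {
  ok_pair <- function(seqs, fwd, rev, size, want) {
    for (s in seqs) {
      amps <- predict_amplicons(s, fwd, rev, max_product = assay$max_product)
      hit <- nrow(amps) && any(abs(amps$length - size) <= assay$size_tolerance)
      if (want && (nrow(amps) != 1L || !hit)) return(FALSE)
      if (!want && nrow(amps) > 0L) return(FALSE)
    }
    TRUE
  }
  ok_pair(ric_seqs, assay$fwd_A, assay$rev_A, assay$size_A, TRUE) &&
    ok_pair(ric_seqs, assay$fwd_B, assay$rev_B, assay$size_B, FALSE) &&
    ok_pair(ino_seqs, assay$fwd_B, assay$rev_B, assay$size_B, TRUE) &&
    ok_pair(ino_seqs, assay$fwd_A, assay$rev_A, assay$size_A, FALSE)
}

.build_pools_once <- function(panel_size, region_length, n_variants_per_species,
                              within_species_snp_rate, assay) {
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, region_length, replace = TRUE)
  footprint_pos <- integer(0)
  anchor_diag <- integer(0)
  if (!is.null(assay)) {
    geom <- .assay_geometry(assay, region_length)
    fp <- geom$footprints
    backbone <- .set_chars(backbone, seq(fp$fwd_A[1], fp$fwd_A[2]),
                           strsplit(assay$fwd_A$sequence, "")[[1]])
    backbone <- .set_chars(backbone, seq(fp$fwd_B[1], fp$fwd_B[2]),
                           strsplit(assay$fwd_B$sequence, "")[[1]])
    backbone <- .set_chars(backbone, seq(fp$rev_A[1], fp$rev_A[2]),
                           strsplit(revcomp(assay$rev_A$sequence), "")[[1]])
    backbone <- .set_chars(backbone, seq(fp$rev_B[1], fp$rev_B[2]),
                           strsplit(revcomp(assay$rev_B$sequence), "")[[1]])
    footprint_pos <- unlist(lapply(fp, function(x) seq(x[1], x[2])))
    # one diagnostic SNP inside each anchor, at its middle base
    anchor_diag <- vapply(geom$anchors, function(a) a[ceiling(length(a) / 2)],
                          integer(1))
  }
  free_pos <- setdiff(seq_len(region_length), footprint_pos)
  n_free_diag <- panel_size - length(anchor_diag)
  diag_pos <- sort(c(anchor_diag,
                     if (n_free_diag > 0) sample(free_pos, n_free_diag)))

  ric_chars <- backbone
  ino_chars <- backbone
  if (!is.null(assay)) {
    # species A (RIC) templates break the species-B primer anchors and
    # vice versa; the broken base is the diagnostic allele of that species
    for (nm in c("fwd_B", "rev_B")) {
      p <- anchor_diag[[nm]]
      ric_chars[p] <- .mutate_base(backbone[p])
    }
    for (nm in c("fwd_A", "rev_A")) {
      p <- anchor_diag[[nm]]
      ino_chars[p] <- .mutate_base(backbone[p])
    }
  }
  for (p in setdiff(diag_pos, anchor_diag)) {
    ino_chars[p] <- .mutate_base(backbone[p])
  }

  variant_sites <- setdiff(free_pos, diag_pos)
  make_variants <- function(ref_chars, prefix) {
    out <- list()
    for (i in seq_len(n_variants_per_species)) {
      hit <- variant_sites[stats::runif(length(variant_sites)) <
                             within_species_snp_rate]
      v <- ref_chars
      for (p in hit) v[p] <- .mutate_base(v[p])
      out[[i]] <- paste(v, collapse = "")
    }
    out
  }
  list(ric_ref = paste(ric_chars, collapse = ""),
       ino_ref = paste(ino_chars, collapse = ""),
       ric_variants = make_variants(ric_chars, "RIC"),
       ino_variants = make_variants(ino_chars, "INO"),
       diag_pos = diag_pos, footprint_pos = footprint_pos)
}

#' Generate the two species allele pools and their diagnostic panel
#'
#' Builds synthetic species-A ("RIC") and species-B ("INO") allele pools whose
#' reference alleles differ at exactly `panel_size` positions, plus
#' within-species variants polymorphic only away from the panel. With an
#' `assay`, the four primer footprints are embedded so that each species'
#' templates amplify only with their own primer pair (see file header).
#'
#' @param panel_size Number of fixed inter-species positions (default 23).
#' @param region_length Length of the region in bp (default 670).
#' @param n_variants_per_species Within-species variant alleles per pool
#'   (default 5).
#' @param within_species_snp_rate Per-site substitution probability for
#'   variants (default 0.005).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param assay A [multiplex_assay()] to embed, or NULL for a plain panel
#'   (required for degenerate/toy configurations). Defaults to the packaged
#'   TROSPA assay.
#' @param max_tries Backbone re-draws allowed before giving up on a
#'   spurious-primer-site-free construction.
#' @return List with elements `ric` and `ino` ([`allele_pool`] lists with
#'   fields marker, species, reference, variants, diagnostic_positions,
#'   footprint_positions) and `table` (a `diagnostic_table` data.frame with
#'   columns reference_id, position, allele_A, allele_B; positions 1-based on
#'   the synthetic reference).
#' @export
generate_allele_pools <- function(panel_size = 23L, region_length = 670L,
                                  n_variants_per_species = 5L,
                                  within_species_snp_rate = 0.005,
                                  seed = 42L,
                                  assay = trospa_assay(),
                                  max_tries = 25L) {
  panel_size <- as.integer(panel_size)
  region_length <- as.integer(region_length)
  if (panel_size > region_length) {
    stop("panel_size exceeds region_length", call. = FALSE)
  }
  if (!is.null(assay) && panel_size < 4L) {
    stop("embedding the assay requires panel_size >= 4 ",
         "(one diagnostic SNP per primer anchor); pass assay = NULL",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  built <- NULL
  for (try in seq_len(max_tries)) {
    cand <- .build_pools_once(panel_size, region_length,
                              n_variants_per_species,
                              within_species_snp_rate, assay)
    if (is.null(assay) ||
        .pool_templates_clean(c(cand$ric_ref, cand$ric_variants),
                              c(cand$ino_ref, cand$ino_variants), assay)) {
      built <- cand
      break
    }
  }
  if (is.null(built)) {
    stop("could not build spurious-site-free templates in ", max_tries,
         " tries", call. = FALSE)
  }

  ref_id <- "SYNTH_TROSPA_REF"
  mk_pool <- function(species, ref_seq, variants) {
    prefix <- if (species == "RIC") "RIC" else "INO"
    ids <- c(paste0(prefix, "_ref"),
             if (length(variants)) paste0(prefix, "_v", seq_along(variants)))
    ms <- marker_set(ids, c(ref_seq, unlist(variants)), marker = "TROSPA",
                     origin = "SYNTH")
    structure(list(marker = "TROSPA", species = species,
                   reference = ms[1, , drop = FALSE],
                   variants = ms[-1, , drop = FALSE],
                   diagnostic_positions = built$diag_pos,
                   footprint_positions = built$footprint_pos),
              class = "allele_pool")
  }
  ric <- mk_pool("RIC", built$ric_ref, built$ric_variants)
  ino <- mk_pool("INO", built$ino_ref, built$ino_variants)
  rc <- strsplit(built$ric_ref, "")[[1]]
  ic <- strsplit(built$ino_ref, "")[[1]]
  tab <- data.frame(reference_id = rep(ref_id, length(built$diag_pos)),
                    position = built$diag_pos,
                    allele_A = rc[built$diag_pos],
                    allele_B = ic[built$diag_pos],
                    stringsAsFactors = FALSE)
  class(tab) <- c("diagnostic_table", "data.frame")
  list(ric = ric, ino = ino, table = tab)
}

#' All alleles of a pool as one marker_set
#'
#' @param pool An `allele_pool`.
#' @return `marker_set` of the reference followed by the variants.
#' @export
pool_alignment <- function(pool) {
  out <- rbind(pool$reference, pool$variants)
  class(out) <- c("marker_set", "data.frame")
  out
}

#' @export
print.allele_pool <- function(x, ...) {
  cat(sprintf("<allele_pool> %s %s: reference + %d variant(s), %d diagnostic position(s)\n",
              x$species, x$marker, nrow(x$variants),
              length(x$diagnostic_positions)))
  invisible(x)
}
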