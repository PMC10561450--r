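# Synthetic 16S rDNA haplotype pool and secondary marker pools.
#
# The 16S pool emulates a mitochondrial fragment with high haplotype
# diversity but no species-fixed differences: 36 unique haplotypes carrying
# a two-position motif (AG / CT / AT) over a 96-99.7% pairwise-identity band.
# Each haplotype owns a private set of 2-7 substitutions relative to a common
# backbone, so any two haplotypes differ at 4-16 sites (within the band for a
# 455 bp fragment) and never collapse to the same string.

#' Default 16S haplotype composition
#'
#' One row per motif label with the number of unique haplotypes per origin and
#' the total number of individual sequences carrying that origin.
#' @return data.frame with columns label, cz_haps, alg_haps.
#' @export
s16_default_counts <- function() {
  data.frame(label = c("AG", "CT", "AT"),
             cz_haps = c(3L, 23L, 0L),
             alg_haps = c(4L, 5L, 1L),
             stringsAsFactors = FALSE)
}

#' Generate the 16S sequence pool
#'
#' @param counts Haplotype composition table as in [s16_default_counts()].
#' @param cz_total,alg_total Total sequences per origin (defaults 222 / 43);
#'   every haplotype receives at least one member.
#' @param length Fragment length in bp (default 455).
#' @param motif_positions The two 1-based motif positions (default c(101, 153)).
#' @param identity_band Permitted pairwise-identity range in percent
#'   (default c(96.02, 99.73)); generation is retried a bounded number of
#'   times if a draw falls outside it.
#' @param private_range Per-haplotype private substitution count range
#'   (default c(2, 7)).
#' @param seed Integer seed.
#' @param max_tries Retry budget before failing with the attempt count.
#' @return List: `seqs` (a `marker_set` of all individual sequences),
#'   `haplotypes` (truth table: hap_id, label, origin, count — for
#'   validation only).
#' @export
generate_16s_pool <- function(counts = s16_default_counts(),
                              cz_total = 222L, alg_total = 43L,
                              length = 455L, motif_positions = c(101L, 153L),
                              identity_band = c(96.02, 99.73),
                              private_range = c(2L, 7L),
                              seed = 42L, max_tries = 10L) {
  stopifnot(identity_band[1] > 0, identity_band[2] <= 100,
            identity_band[1] < identity_band[2])
  n_cz_h <- sum(counts$cz_haps); n_alg_h <- sum(counts$alg_haps)
  n_h <- n_cz_h + n_alg_h
  if (cz_total < n_cz_h || alg_total < n_alg_h) {
    stop("origin totals smaller than haplotype counts", call. = FALSE)
  }
  # feasibility: worst-case pair differs at 2*max_private + 2 motif sites
  max_diff <- floor((100 - identity_band[1]) / 100 * length)
  min_diff <- ceiling((100 - identity_band[2]) / 100 * length)
  if (2L * private_range[2] + 2L > max_diff || 2L * private_range[1] < min_diff) {
    stop("private_range infeasible for the identity band at this length",
         call. = FALSE)
  }
  if (n_h * private_range[2] + 2L > length) {
    stop("not enough positions for private substitutions", call. = FALSE)
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  for (attempt in seq_len(max_tries)) {
    backbone <- sample(bases, length, replace = TRUE)
    free <- setdiff(seq_len(length), motif_positions)
    free <- sample(free)  # shuffled allocation pool for private sites
    hap <- list(); hap_meta <- list(); used <- 0L
    idx <- 0L
    for (r in seq_len(nrow(counts))) {
      lab <- counts$label[r]
      m1 <- substr(lab, 1, 1); m2 <- substr(lab, 2, 2)
      for (org in c("CZ", "ALG")) {
        n_this <- if (org == "CZ") counts$cz_haps[r] else counts$alg_haps[r]
        for (h in seq_len(n_this)) {
          idx <- idx + 1L
          k <- sample(seq(private_range[1], private_range[2]), 1L)
          sites <- free[used + seq_len(k)]; used <- used + k
          chars <- backbone
          chars[motif_positions[1]] <- m1
          chars[motif_positions[2]] <- m2
          for (p in sites) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
          hap[[idx]] <- paste(chars, collapse = "")
          hap_meta[[idx]] <- data.frame(hap_id = sprintf("H%02d", idx),
                                        label = lab, origin = org,
                                        stringsAsFactors = FALSE)
        }
      }
    }
    seqs <- unlist(hap)
    if (anyDuplicated(seqs)) next
    pid <- pairwise_identity_matrix(seqs)
    off <- pid[upper.tri(pid)]
    if (all(off >= identity_band[1] & off <= identity_band[2])) {
      meta <- do.call(rbind, hap_meta)
      # distribute members: every haplotype >= 1, remainder multinomial
      spread <- function(total, which_idx) {
        cnt <- rep(1L, length(which_idx))
        extra <- total - length(which_idx)
        if (extra > 0) {
          add <- table(factor(sample(seq_along(which_idx), extra, replace = TRUE),
                              levels = seq_along(which_idx)))
          cnt <- cnt + as.integer(add)
        }
        cnt
      }
      meta$count <- 0L
      cz_idx <- which(meta$origin == "CZ"); alg_idx <- which(meta$origin == "ALG")
      meta$count[cz_idx] <- spread(cz_total, cz_idx)
      meta$count[alg_idx] <- spread(alg_total, alg_idx)
      ids <- character(0); seq_out <- character(0); org_out <- character(0)
      for (i in seq_len(nrow(meta))) {
        n <- meta$count[i]
        ids <- c(ids, sprintf("S16_%s_%s_%02d", meta$origin[i], meta$hap_id[i],
                              seq_len(n)))
        seq_out <- c(seq_out, rep(seqs[i], n))
        org_out <- c(org_out, rep(meta$origin[i], n))
      }
      ms <- marker_set(ids, seq_out, marker = "S16", origin = org_out)
      return(list(seqs = ms, haplotypes = meta,
                  motif_positions = as.integer(motif_positions)))
    }
  }
  stop("16S pool generation failed the identity band after ", max_tries,
       " attempts", call. = FALSE)
}

#' Generate a labelled two-species pool for a secondary marker
#'
#' Species pools share a random backbone; `n_fixed_diffs` positions are fixed
#' inter-species differences and each allele carries private substitutions at
#' the given per-site rate elsewhere. `n_fixed_diffs = 0` yields a marker with
#' no discriminating signal (the calreticulin-like negative control).
#'
#' @param marker Marker name (one of S16, COI, ITS2, CALR).
#' @param length Fragment length in bp.
#' @param n_fixed_diffs Number of species-fixed difference positions.
#' @param n_alleles_per_species Alleles per species pool.
#' @param snp_rate Per-site private substitution probability.
#' @param seed Integer seed.
#' @return List with `ric` and `alg` ... two `marker_set`s named `ric`/`ino`.
#' @export
generate_marker_pool <- function(marker, length, n_fixed_diffs,
                                 n_alleles_per_species = 5L, snp_rate = 0.004,
                                 seed = 42L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, length, replace = TRUE)
  fixed <- if (n_fixed_diffs > 0) sort(sample(seq_len(length), n_fixed_diffs)) else integer(0)
  ino_chars <- backbone
  for (p in fixed) ino_chars[p] <- sample(setdiff(bases, backbone[p]), 1L)
  free <- setdiff(seq_len(length), fixed)
  mk <- function(ref_chars, species) {
    seqs <- vapply(seq_len(n_alleles_per_species), function(i) {
      hit <- free[stats::runif(base::length(free)) < snp_rate]
      v <- ref_chars
      for (p in hit) v[p] <- sample(setdiff(bases, v[p]), 1L)
      paste(v, collapse = "")
    }, "")
    marker_set(sprintf("%s_%s_%d", marker, species, seq_len(n_alleles_per_species)),
               seqs, marker = marker, origin = "SYNTH")
  }
  list(ric = mk(backbone, "RIC"), ino = mk(ino_chars, "INO"),
       fixed_positions = fixed)
}

#' Default secondary-marker profiles
#'
#' Divergence profile used by the study fixture: ITS2 and COI separate the
#' species (8 and 5 fixed differences), 16S and the calreticulin-like marker
#' do not (0 fixed differences).
#'
#' @param seed Integer seed (sub-seeds are derived per marker).
#' @return Named list of [generate_marker_pool()] results.
#' @export
default_marker_pools <- function(seed = 42L) {
  list(
    ITS2 = generate_marker_pool("ITS2", 400L, 8L, seed = seed + 1L),
    COI  = generate_marker_pool("COI", 600L, 5L, seed = seed + 2L),
    S16  = generate_marker_pool("S16", 455L, 0L, seed = seed + 3L),
    CALR = generate_marker_pool("CALR", 500L, 0L, seed = seed + 4L))
}
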