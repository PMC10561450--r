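# Synthetic cohort and chromatogram-like traces.
#
# The generator plants a survey cohort with known composition: pure species-A
# ("RIC") and species-B ("INO") individuals homozygous for one pool allele,
# and hybrids carrying one reference allele of each species. Traces are
# 4-channel per-position peak-height tables for both sequencing strands.
# Non-hybrid traces carry a configured number of noise double peaks at
# random non-diagnostic positions (emulating the sporadic heterozygosity of
# a nuclear intron); hybrid traces are heterozygous at every diagnostic
# position plus random extras up to a configured total.

#' Specify a cohort composition
#'
#' @param localities data.frame with columns locality, origin (CZ/ALG) and
#'   per-sex class counts ric_f, ric_m, hyb_f, hyb_m, ino_f, ino_m.
#' @param zero_noise_fraction Fraction of non-hybrid samples whose trace has
#'   no double peaks at all (applied as an exact count,
#'   `round(fraction * n_nonhybrid)`).
#' @param noise_range Inclusive range of noise double-peak counts for the
#'   remaining non-hybrids (default 1--15).
#' @param hybrid_peaks_range Inclusive range of TOTAL double peaks per hybrid
#'   (default 25--32); the lower bound must be at least the panel size.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(localities, zero_noise_fraction = 0.1,
                        noise_range = c(1L, 15L),
                        hybrid_peaks_range = c(25L, 32L), seed = 42L) {
  need <- c("locality", "origin", "ric_f", "ric_m", "hyb_f", "hyb_m",
            "ino_f", "ino_m")
  stopifnot(all(need %in% names(localities)))
  counts <- as.matrix(localities[, need[-(1:2)]])
  if (any(counts < 0)) stop("negative class count", call. = FALSE)
  if (noise_range[1] < 0 || noise_range[1] > noise_range[2]) {
    stop("invalid noise_range", call. = FALSE)
  }
  if (hybrid_peaks_range[1] > hybrid_peaks_range[2]) {
    stop("invalid hybrid_peaks_range", call. = FALSE)
  }
  structure(list(localities = localities,
                 zero_noise_fraction = zero_noise_fraction,
                 noise_range = as.integer(noise_range),
                 hybrid_peaks_range = as.integer(hybrid_peaks_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The default study cohort composition
#'
#' Four localities, 374 ticks: 321 species-A (153 F / 168 M), 10 hybrids
#' (6 F / 4 M, all CZ), 43 species-B (20 F / 23 M, all ALG).
#'
#' @param seed Integer seed.
#' @param ... Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
study_cohort_spec <- function(seed = 42L, ...) {
  loc <- data.frame(
    locality = c("CZ_Libava", "CZ_Podyji", "CZ_Prostredni_Porici", "ALG_El_Tarf"),
    origin = c("CZ", "CZ", "CZ", "ALG"),
    ric_f = c(55L, 45L, 49L, 4L), ric_m = c(55L, 54L, 59L, 0L),
    hyb_f = c(3L, 2L, 1L, 0L), hyb_m = c(1L, 2L, 1L, 0L),
    ino_f = c(0L, 0L, 0L, 20L), ino_m = c(0L, 0L, 0L, 23L),
    stringsAsFactors = FALSE)
  cohort_spec(loc, seed = seed, ...)
}

#' The sequenced-subset composition (140 traces)
#'
#' Emulates the subset of the cohort that is Sanger-sequenced for the
#' double-peak triage: 112 species-A, 18 species-B and the 10 hybrids
#' (140 samples), of which exactly 13 non-hybrids carry no double peaks,
#' 117 carry 1--15, and the hybrids carry 25--32.
#'
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
sequenced_subset_spec <- function(seed = 42L) {
  loc <- data.frame(
    locality = c("CZ_Libava", "CZ_Podyji", "CZ_Prostredni_Porici", "ALG_El_Tarf"),
    origin = c("CZ", "CZ", "CZ", "ALG"),
    ric_f = c(20L, 18L, 17L, 4L), ric_m = c(20L, 17L, 16L, 0L),
    hyb_f = c(3L, 2L, 1L, 0L), hyb_m = c(1L, 2L, 1L, 0L),
    ino_f = c(0L, 0L, 0L, 9L), ino_m = c(0L, 0L, 0L, 9L),
    stringsAsFactors = FALSE)
  cohort_spec(loc, zero_noise_fraction = 13 / 130, seed = seed)
}

# peak-height model: strong primary channel, near-baseline others; a
# heterozygous position carries a secondary channel at >= `ratio` of primary
.PRIMARY_H <- c(800, 1200)
.BASELINE_H <- c(5, 40)
.SECONDARY_MAX <- 0.95

.channel_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.strand_heights <- function(primary, secondary_of) {
  n <- length(primary)
  h <- matrix(stats::runif(4L * n, .BASELINE_H[1], .BASELINE_H[2]),
              nrow = n, ncol = 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  prim_h <- stats::runif(n, .PRIMARY_H[1], .PRIMARY_H[2])
  h[cbind(seq_len(n), .channel_idx[primary])] <- prim_h
  het <- which(!is.na(secondary_of$base))
  if (length(het)) {
    sec_h <- prim_h[het] * stats::runif(length(het), secondary_of$ratio[het],
                                        .SECONDARY_MAX)
    h[cbind(het, .channel_idx[secondary_of$base[het]])] <- sec_h
  }
  h
}

#' Emulate a both-strand Sanger-like trace for a diploid genotype
#'
#' Positions where the two alleles differ become double peaks, as do the
#' injected `noise_positions` (secondary base drawn at random there). The
#' secondary/primary height ratio at every double peak is at least
#' `peak_ratio_het` on both strands; everything else sits near baseline.
#' The reverse-strand table holds the heights as read on the minus strand
#' (channels are complement bases), indexed by plus-strand position.
#'
#' @param genotype Character vector of two equal-length gap-free allele
#'   sequences.
#' @param noise_positions Integer positions (1-based) to render heterozygous
#'   beyond the genotype's own differences.
#' @param peak_ratio_het Minimum secondary/primary ratio at a double peak
#'   (default 0.6).
#' @param sample_id Trace identifier.
#' @param seed Optional seed; omit when calling under an outer RNG stream.
#' @return A `chromatogram` list: sample_id, length, forward and reverse
#'   height matrices (positions x channels A,C,G,T).
#' @export
emulate_trace <- function(genotype, noise_positions = integer(0),
                          peak_ratio_het = 0.6, sample_id = "trace",
                          seed = NULL) {
  stopifnot(length(genotype) == 2L, nchar(genotype[1]) == nchar(genotype[2]))
  if (!is.null(seed)) set.seed(as.integer(seed))
  a1 <- strsplit(toupper(genotype[1]), "")[[1]]
  a2 <- strsplit(toupper(genotype[2]), "")[[1]]
  n <- length(a1)
  primary <- a1
  secondary <- rep(NA_character_, n)
  het <- which(a1 != a2)
  secondary[het] <- a2[het]
  noise_positions <- setdiff(as.integer(noise_positions), het)
  for (p in noise_positions) {
    secondary[p] <- sample(setdiff(c("A", "C", "G", "T"), primary[p]), 1L)
  }
  ratio <- rep(peak_ratio_het, n)
  sec <- list(base = secondary, ratio = ratio)
  fwd <- .strand_heights(primary, sec)
  rev_primary <- unname(.COMPLEMENT[primary])
  rev_sec <- list(base = ifelse(is.na(secondary), NA_character_,
                                unname(.COMPLEMENT[secondary])),
                  ratio = ratio)
  rev <- .strand_heights(rev_primary, rev_sec)
  structure(list(sample_id = sample_id, length = n,
                 forward = fwd, reverse = rev),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d positions x 2 strands x 4 channels\n",
              x$sample_id, x$length))
  invisible(x)
}

#' Write / read a trace in the package TSV dialect
#'
#' Long format with columns position, strand (F/R), A, C, G, T.
#' @param trace A `chromatogram`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  tab <- rbind(
    data.frame(position = seq_len(trace$length), strand = "F",
               trace$forward, stringsAsFactors = FALSE),
    data.frame(position = seq_len(trace$length), strand = "R",
               trace$reverse, stringsAsFactors = FALSE))
  write_tsv(tab, path)
}

#' @param sample_id Identifier to attach on read.
#' @rdname write_trace
#' @export
read_trace <- function(path, sample_id = basename(path)) {
  tab <- read_tsv(path)
  f <- as.matrix(tab[tab$strand == "F", c("A", "C", "G", "T")])
  r <- as.matrix(tab[tab$strand == "R", c("A", "C", "G", "T")])
  rownames(f) <- rownames(r) <- NULL
  structure(list(sample_id = sub("\\.tsv$", "", sample_id), length = nrow(f),
                 forward = f, reverse = r),
            class = "chromatogram")
}

.draw_allele <- function(aln) {
  aln$sequence[sample.int(nrow(aln), 1L)]
}

#' Generate a full synthetic cohort with traces
#'
#' Individuals are laid out per the spec's locality table. Non-hybrids are
#' homozygous for one allele drawn from their species pool and receive either
#' zero noise double peaks (an exact `zero_noise_fraction` share of them) or
#' a count drawn uniformly from `noise_range`, placed at random non-diagnostic
#' positions. Hybrids carry the two species reference alleles (heterozygous at
#' every diagnostic position) plus extra noise peaks up to a total drawn from
#' `hybrid_peaks_range`.
#'
#' @param spec A [cohort_spec()].
#' @param pools Result of [generate_allele_pools()].
#' @param peak_ratio_het Passed to [emulate_trace()].
#' @return A `cohort` list: `individuals` (data.frame with sample_id,
#'   locality, origin, sex, true_class, allele1_id, allele2_id, allele1,
#'   allele2, n_planted_peaks) and `traces` (named list of `chromatogram`s).
#'   `true_class` and `n_planted_peaks` are generator truth, for validation
#'   only — no classifier reads them.
#' @export
generate_cohort <- function(spec, pools, peak_ratio_het = 0.6) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  panel <- pools$ric$diagnostic_positions
  region_len <- nchar(pools$ric$reference$sequence)
  if (length(panel) &&
      spec$hybrid_peaks_range[1] < length(panel)) {
    stop("hybrid_peaks_range lower bound below panel size", call. = FALSE)
  }
  if (spec$noise_range[2] > region_len - length(panel)) {
    stop("noise_range exceeds available non-diagnostic positions", call. = FALSE)
  }
  ric_aln <- pool_alignment(pools$ric)
  ino_aln <- pool_alignment(pools$ino)
  nonpanel <- setdiff(seq_len(region_len), panel)

  rows <- list(); traces <- list()
  counter <- 0L
  loc_tab <- spec$localities
  for (i in seq_len(nrow(loc_tab))) {
    loc <- loc_tab$locality[i]; org <- loc_tab$origin[i]
    classes <- c(rep("RIC", loc_tab$ric_f[i]), rep("RIC", loc_tab$ric_m[i]),
                 rep("HYB", loc_tab$hyb_f[i]), rep("HYB", loc_tab$hyb_m[i]),
                 rep("INO", loc_tab$ino_f[i]), rep("INO", loc_tab$ino_m[i]))
    sexes <- c(rep("F", loc_tab$ric_f[i]), rep("M", loc_tab$ric_m[i]),
               rep("F", loc_tab$hyb_f[i]), rep("M", loc_tab$hyb_m[i]),
               rep("F", loc_tab$ino_f[i]), rep("M", loc_tab$ino_m[i]))
    for (k in seq_along(classes)) {
      counter <- counter + 1L
      sid <- sprintf("T%03d%s", counter, sexes[k])
      cls <- classes[k]
      if (cls == "HYB") {
        a1 <- pools$ric$reference$sequence; a1_id <- pools$ric$reference$sample_id
        a2 <- pools$ino$reference$sequence; a2_id <- pools$ino$reference$sample_id
      } else {
        aln <- if (cls == "RIC") ric_aln else ino_aln
        pick <- sample.int(nrow(aln), 1L)
        a1 <- a2 <- aln$sequence[pick]
        a1_id <- a2_id <- aln$sample_id[pick]
      }
      rows[[counter]] <- data.frame(
        sample_id = sid, locality = loc, origin = org, sex = sexes[k],
        true_class = cls, allele1_id = a1_id, allele2_id = a2_id,
        allele1 = a1, allele2 = a2, n_planted_peaks = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (counter == 0L) {
    ind <- data.frame(sample_id = character(), locality = character(),
                      origin = character(), sex = character(),
                      true_class = character(), allele1_id = character(),
                      allele2_id = character(), allele1 = character(),
                      allele2 = character(), n_planted_peaks = integer(),
                      stringsAsFactors = FALSE)
    return(structure(list(individuals = ind, traces = list(), spec = spec),
                     class = "cohort"))
  }
  ind <- do.call(rbind, rows)

  # exact zero-noise share among non-hybrids
  nonhyb <- which(ind$true_class != "HYB")
  n_zero <- round(spec$zero_noise_fraction * length(nonhyb))
  zero_idx <- if (n_zero > 0) sample(nonhyb, n_zero) else integer(0)
  for (j in seq_len(nrow(ind))) {
    if (ind$true_class[j] == "HYB") {
      total <- sample(seq(spec$hybrid_peaks_range[1],
                          spec$hybrid_peaks_range[2]), 1L)
      extras <- sample(nonpanel, total - length(panel))
      noise <- extras
      planted <- total
    } else if (j %in% zero_idx) {
      noise <- integer(0); planted <- 0L
    } else {
      k <- sample(seq(spec$noise_range[1], spec$noise_range[2]), 1L)
      noise <- sample(nonpanel, k); planted <- k
    }
    ind$n_planted_peaks[j] <- planted
    traces[[ind$sample_id[j]]] <- emulate_trace(
      c(ind$allele1[j], ind$allele2[j]), noise_positions = noise,
      peak_ratio_het = peak_ratio_het, sample_id = ind$sample_id[j])
  }
  structure(list(individuals = ind, traces = traces, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals (%s)\n", nrow(x$individuals),
              paste(names(table(x$individuals$true_class)),
                    table(x$individuals$true_class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' TROSPA sequences of a cohort as FASTA-writable marker_set
#'
#' One record per allele, ids suffixed `_a1`/`_a2`.
#' @param cohort A `cohort`.
#' @return A `marker_set`.
#' @export
cohort_trospa_alleles <- function(cohort) {
  ind <- cohort$individuals
  marker_set(
    sample_id = c(paste0(ind$sample_id, "_a1"), paste0(ind$sample_id, "_a2")),
    sequence = c(ind$allele1, ind$allele2),
    marker = "TROSPA",
    origin = rep(ind$origin, 2L),
    sex = rep(ind$sex, 2L))
}
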