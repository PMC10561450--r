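# End-to-end pipeline: generate -> in-silico PCR -> diagnose -> type,
# producing a survey-style cohort report plus all intermediate artifacts.

.GEL_TO_CALL <- c(SPECIES_A = "RIC", SPECIES_B = "INO", HYBRID = "HYBRID",
                  NONE = "NONE")

#' Default pipeline configuration
#'
#' @param seed Integer seed.
#' @param outdir Output directory for artifacts.
#' @param sequence_subset Emulate only the sequenced subset (140 traces)
#'   instead of the full cohort (default FALSE).
#' @return Config list accepted by [run_pipeline()].
#' @export
default_study_config <- function(seed = 42L, outdir = tempfile("tickhybrid_"),
                                 sequence_subset = FALSE) {
  list(seed = as.integer(seed), outdir = outdir,
       sequence_subset = isTRUE(sequence_subset),
       panel = list(size = 23L, region_length = 670L,
                    n_variants_per_species = 5L, snp_rate = 0.005),
       thresholds = list(similarity = 0.30, height = 0.50,
                         hybrid_min_fraction = 0.85, max_noise_het = 15L),
       write_traces = FALSE,
       s16 = TRUE)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  need <- c("seed", "outdir")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  defaults <- default_study_config(seed = config$seed, outdir = config$outdir)
  out <- utils::modifyList(defaults, config)
  out
}

#' Gel-classify every individual of a cohort
#'
#' @param cohort A `cohort`.
#' @param assay A [multiplex_assay()].
#' @return data.frame: sample_id, locality, sex, bands, gel_verdict.
#' @export
gel_screen <- function(cohort, assay) {
  ind <- cohort$individuals
  res <- lapply(seq_len(nrow(ind)), function(i) {
    g <- multiplex_gel(c(ind$allele1[i], ind$allele2[i]), assay)
    data.frame(sample_id = ind$sample_id[i], locality = ind$locality[i],
               sex = ind$sex[i],
               bands = paste(g$bands, collapse = ","),
               gel_verdict = g$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sequence-diagnose every trace of a cohort
#'
#' Runs double-peak detection, consensus calling and species/hybrid calling
#' against a diagnostic table.
#'
#' @param cohort A `cohort`.
#' @param table A `diagnostic_table`.
#' @param settings A [peak_call_settings()].
#' @param hybrid_min_fraction,max_noise_het Passed to [call_sample()].
#' @return data.frame: sample_id, n_double_peaks, n_on_panel, matched_fraction,
#'   call_verdict.
#' @export
diagnose_cohort <- function(cohort, table, settings = peak_call_settings(),
                            hybrid_min_fraction = 0.85, max_noise_het = 15L) {
  res <- lapply(cohort$traces, function(tr) {
    cl <- call_sample(tr, table, settings,
                      hybrid_min_fraction = hybrid_min_fraction,
                      max_noise_het = max_noise_het)
    data.frame(sample_id = cl$sample_id,
               n_double_peaks = length(cl$double_peak_positions),
               n_on_panel = cl$n_diagnostic_het,
               matched_fraction = cl$matched_fraction,
               call_verdict = cl$verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-tabulate gel verdicts against sequence verdicts
#'
#' @param gel_report Output of [gel_screen()].
#' @param call_report Output of [diagnose_cohort()].
#' @return List: `matrix` (gel class x sequence class counts) and
#'   `discrepancies` (rows where the two disagree after mapping gel
#'   SPECIES_A/SPECIES_B to RIC/INO).
#' @export
summarize_concordance <- function(gel_report, call_report) {
  if (nrow(gel_report) == 0L && nrow(call_report) == 0L) {
    return(list(matrix = matrix(0L, 0, 0), discrepancies = data.frame()))
  }
  orphans <- c(setdiff(gel_report$sample_id, call_report$sample_id),
               setdiff(call_report$sample_id, gel_report$sample_id))
  if (length(orphans)) {
    stop("reports do not share sample ids; orphans: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  m <- merge(gel_report[, c("sample_id", "gel_verdict")],
             call_report[, c("sample_id", "call_verdict")], by = "sample_id")
  gel_lv <- c("SPECIES_A", "SPECIES_B", "HYBRID", "NONE")
  call_lv <- c("RIC", "INO", "HYBRID", "INDETERMINATE")
  mat <- table(factor(m$gel_verdict, levels = gel_lv),
               factor(m$call_verdict, levels = call_lv))
  mapped <- unname(.GEL_TO_CALL[m$gel_verdict])
  disc <- m[mapped != m$call_verdict, , drop = FALSE]
  list(matrix = unclass(mat), discrepancies = disc)
}

.peak_histogram <- function(n_peaks) {
  bins <- c("0", "1-15", "16-24", "25-32", ">32")
  cut_bin <- function(n) {
    if (n == 0) "0" else if (n <= 15) "1-15" else if (n <= 24) "16-24"
    else if (n <= 32) "25-32" else ">32"
  }
  tab <- table(factor(vapply(n_peaks, cut_bin, ""), levels = bins))
  stats::setNames(as.integer(tab), bins)
}

.locality_table <- function(gel_report) {
  locs <- unique(gel_report$locality)
  rows <- lapply(locs, function(L) {
    g <- gel_report[gel_report$locality == L, ]
    cnt <- function(v, s) sum(g$gel_verdict == v & g$sex == s)
    data.frame(locality = L, n = nrow(g),
               ric_f = cnt("SPECIES_A", "F"), ric_m = cnt("SPECIES_A", "M"),
               hyb_f = cnt("HYBRID", "F"), hyb_m = cnt("HYBRID", "M"),
               ino_f = cnt("SPECIES_B", "F"), ino_m = cnt("SPECIES_B", "M"),
               none = sum(g$gel_verdict == "NONE"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' Stages: allele-pool generation, cohort generation, multiplex gel screen,
#' diagnostic-SNP discovery, trace diagnosis, gel/sequence concordance,
#' hybrid phasing with nearest-reference assignment, and (optionally) 16S
#' pool dereplication and motif typing. All tabular artifacts are written
#' under `config$outdir`; the run is a pure function of the config (seed
#' included).
#'
#' @param config Config list or YAML file path; see [default_study_config()].
#' @return A `cohort_report` list: localities, totals, histogram, concordance,
#'   plus the underlying reports (gel, calls, phasing, s16) and the discovered
#'   diagnostic table.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  assay <- trospa_assay()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  pools <- stage("allele_pools", generate_allele_pools(
    panel_size = cfg$panel$size, region_length = cfg$panel$region_length,
    n_variants_per_species = cfg$panel$n_variants_per_species,
    within_species_snp_rate = cfg$panel$snp_rate,
    seed = cfg$seed, assay = assay))

  spec <- if (!is.null(cfg$cohort)) {
    # inline composition override (a data.frame or a list of locality rows,
    # as parsed from YAML)
    loc <- if (is.data.frame(cfg$cohort)) cfg$cohort
           else do.call(rbind, lapply(cfg$cohort, as.data.frame))
    cohort_spec(loc, seed = cfg$seed)
  } else if (cfg$sequence_subset) {
    sequenced_subset_spec(seed = cfg$seed)
  } else {
    study_cohort_spec(seed = cfg$seed)
  }
  cohort <- stage("cohort", generate_cohort(spec, pools))
  ind <- cohort$individuals
  if (nrow(ind) == 0L) {
    empty <- structure(list(localities = data.frame(), totals = data.frame(),
                            histogram = .peak_histogram(integer(0)),
                            concordance = list(matrix = matrix(0L, 0, 0),
                                               discrepancies = data.frame()),
                            gel = data.frame(), calls = data.frame(),
                            phasing = data.frame(), s16 = NULL,
                            table = pools$table),
                       class = "cohort_report")
    return(empty)
  }
  write_fasta(cohort_trospa_alleles(cohort),
              file.path(cfg$outdir, "trospa_alleles.fasta"))
  if (isTRUE(cfg$write_traces)) {
    tdir <- file.path(cfg$outdir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (tr in cohort$traces) {
      write_trace(tr, file.path(tdir, paste0(tr$sample_id, ".tsv")))
    }
  }

  gel <- stage("gel_screen", gel_screen(cohort, assay))
  write_tsv(gel, file.path(cfg$outdir, "gel_report.tsv"))

  # panel discovery is re-done from the labelled alignments; the generator's
  # own table is never used downstream
  table <- stage("snp_discovery", find_diagnostic_snps(
    pool_alignment(pools$ric), pool_alignment(pools$ino)))
  write_tsv(as.data.frame(table), file.path(cfg$outdir, "diagnostic_panel.tsv"))

  settings <- peak_call_settings(
    similarity_threshold = cfg$thresholds$similarity,
    height_threshold = cfg$thresholds$height)
  calls <- stage("diagnose", diagnose_cohort(
    cohort, table, settings,
    hybrid_min_fraction = cfg$thresholds$hybrid_min_fraction,
    max_noise_het = cfg$thresholds$max_noise_het))
  write_tsv(calls, file.path(cfg$outdir, "calls_report.tsv"))

  conc <- stage("concordance", summarize_concordance(gel, calls))
  if (nrow(conc$discrepancies)) {
    write_tsv(conc$discrepancies, file.path(cfg$outdir, "discrepancies.tsv"))
  }

  # phase every hybrid-called sample and place both haplotypes
  tro_panel <- pool_reference_panel(pools)
  hyb_ids <- calls$sample_id[calls$call_verdict == "HYBRID"]
  phasing <- stage("phasing", {
    rows <- lapply(hyb_ids, function(sid) {
      cons <- consensus_with_ambiguities(cohort$traces[[sid]], settings)
      hp <- phase_hybrid(cons, table, sample_id = sid)
      a1 <- assign_by_nearest_reference(hp$haplotype_1, tro_panel)
      a2 <- assign_by_nearest_reference(hp$haplotype_2, tro_panel)
      data.frame(sample_id = sid,
                 hap1_label = a1$label, hap1_margin = a1$margin,
                 hap2_label = a2$label, hap2_margin = a2$margin,
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else data.frame()
  })
  if (nrow(phasing)) write_tsv(phasing, file.path(cfg$outdir, "phasing_report.tsv"))

  s16 <- NULL
  if (isTRUE(cfg$s16)) {
    s16 <- stage("s16_typing", {
      pool <- generate_16s_pool(seed = cfg$seed)
      recs <- dereplicate(pool$seqs)
      recs$motif <- vapply(recs$sequence, type_haplotype, "",
                           motif_positions = pool$motif_positions)
      write_fasta(pool$seqs, file.path(cfg$outdir, "s16_pool.fasta"))
      write_tsv(recs[, c("haplotype_id", "count", "origins", "motif")],
                file.path(cfg$outdir, "s16_haplotypes.tsv"))
      recs
    })
  }

  localities <- .locality_table(gel)
  totals <- data.frame(locality = "Total", n = sum(localities$n),
                       t(colSums(localities[, -(1:2)])))
  hist <- .peak_histogram(calls$n_double_peaks)

  # report invariants
  stopifnot(all(localities$n ==
                  rowSums(localities[, c("ric_f", "ric_m", "hyb_f", "hyb_m",
                                         "ino_f", "ino_m", "none")])))
  stopifnot(sum(conc$matrix) == nrow(ind))
  report <- structure(list(localities = localities, totals = totals,
                           histogram = hist, concordance = conc,
                           gel = gel, calls = calls, phasing = phasing,
                           s16 = s16, table = table),
                      class = "cohort_report")
  write_tsv(rbind(localities, totals), file.path(cfg$outdir, "cohort_report.tsv"))
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  if (nrow(x$localities)) {
    print.data.frame(rbind(x$localities, x$totals), row.names = FALSE)
    cat("double-peak histogram: ",
        paste(names(x$histogram), x$histogram, sep = "=", collapse = "  "),
        "\n")
  } else {
    cat("(empty cohort)\n")
  }
  invisible(x)
}
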