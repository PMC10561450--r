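test_that("the study composition plants 374 individuals in the printed classes", {
  pools <- fixture_pools()
  cohort <- generate_cohort(study_cohort_spec(seed = 42), pools)
  ind <- cohort$individuals
  expect_identical(nrow(ind), 374L)
  expect_identical(sum(ind$true_class == "RIC"), 321L)
  expect_identical(sum(ind$true_class == "INO"), 43L)
  expect_identical(sum(ind$true_class == "HYB"), 10L)
  expect_true(all(ind$origin[ind$true_class == "INO"] == "ALG"))
  expect_true(all(ind$origin[ind$true_class == "HYB"] == "CZ"))
  # per-locality, per-sex layout
  lib <- ind[ind$locality == "CZ_Libava", ]
  expect_identical(sum(lib$true_class == "RIC" & lib$sex == "F"), 55L)
  expect_identical(sum(lib$true_class == "HYB" & lib$sex == "M"), 1L)
})

test_that("a zero-count spec yields an empty cohort", {
  loc <- study_cohort_spec()$localities
  loc[, -(1:2)] <- 0L
  cohort <- generate_cohort(cohort_spec(loc), fixture_pools())
  expect_identical(nrow(cohort$individuals), 0L)
  expect_length(cohort$traces, 0)
})

test_that("same seed reruns are byte-identical on disk", {
  pools <- fixture_pools()
  loc <- data.frame(locality = "L", origin = "CZ", ric_f = 2L, ric_m = 0L,
                    hyb_f = 1L, hyb_m = 0L, ino_f = 2L, ino_m = 0L)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  c1 <- generate_cohort(cohort_spec(loc, seed = 5), pools)
  c2 <- generate_cohort(cohort_spec(loc, seed = 5), pools)
  write_fasta(cohort_trospa_alleles(c1), f1)
  write_fasta(cohort_trospa_alleles(c2), f2)
  write_trace(c1$traces[[1]], t1)
  write_trace(c2$traces[[1]], t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("trace emulation plants exactly the intended double peaks", {
  pools <- fixture_pools()
  ric <- pools$ric$reference$sequence
  ino <- pools$ino$reference$sequence
  # homozygous, no noise: nothing to detect
  expect_identical(nrow(detect_double_peaks(emulate_trace(c(ric, ric), seed = 1))), 0L)
  # hybrid: exactly the diagnostic positions, with the species base pairs
  pk <- detect_double_peaks(emulate_trace(c(ric, ino), seed = 2))
  expect_identical(pk$position, pools$table$position)
  expect_identical(pk$base1, pmin(pools$table$allele_A, pools$table$allele_B))
  expect_identical(pk$base2, pmax(pools$table$allele_A, pools$table$allele_B))
  # planted noise at named positions is recovered exactly
  noise <- c(12L, 90L, 250L, 400L, 666L)
  pk2 <- detect_double_peaks(emulate_trace(c(ric, ric), noise_positions = noise,
                                           seed = 3))
  expect_identical(pk2$position, noise)
})

test_that("trace round-trip through the TSV dialect preserves detection", {
  pools <- fixture_pools()
  tr <- emulate_trace(c(pools$ric$reference$sequence,
                        pools$ino$reference$sequence), seed = 4,
                      sample_id = "rt")
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- read_trace(f, sample_id = "rt")
  expect_equal(back$forward, tr$forward, tolerance = 1e-12)
  expect_identical(detect_double_peaks(back)$position,
                   detect_double_peaks(tr)$position)
})

test_that("noise-free classification recovers every planted class (round trip)", {
  pools <- fixture_pools()
  tab <- fixture_table()
  assay <- trospa_assay()
  loc <- data.frame(locality = c("L1", "L2"), origin = c("CZ", "ALG"),
                    ric_f = c(3L, 1L), ric_m = c(2L, 0L),
                    hyb_f = c(2L, 0L), hyb_m = c(1L, 0L),
                    ino_f = c(0L, 3L), ino_m = c(0L, 2L))
  cohort <- generate_cohort(cohort_spec(loc, seed = 11), pools)
  gel <- gel_screen(cohort, assay)
  calls <- diagnose_cohort(cohort, tab)
  truth <- cohort$individuals$true_class
  map_gel <- c(SPECIES_A = "RIC", SPECIES_B = "INO", HYBRID = "HYB")
  map_call <- c(RIC = "RIC", INO = "INO", HYBRID = "HYB")
  expect_identical(unname(map_gel[gel$gel_verdict]), truth)
  expect_identical(unname(map_call[calls$call_verdict]), truth)
})

test_that("hybrid totals honour the configured double-peak range", {
  pools <- fixture_pools()
  loc <- data.frame(locality = "L", origin = "CZ", ric_f = 0L, ric_m = 0L,
                    hyb_f = 5L, hyb_m = 5L, ino_f = 0L, ino_m = 0L)
  cohort <- generate_cohort(cohort_spec(loc, seed = 21), pools)
  n_pk <- vapply(cohort$traces, function(tr) nrow(detect_double_peaks(tr)), 1L)
  expect_true(all(n_pk >= 25 & n_pk <= 32))
  expect_identical(unname(n_pk), cohort$individuals$n_planted_peaks)
})

test_that("infeasible cohort ranges raise config errors", {
  pools <- fixture_pools()
  loc <- study_cohort_spec()$localities
  expect_error(generate_cohort(cohort_spec(loc, hybrid_peaks_range = c(10, 32)),
                               pools), "panel size")
  expect_error(generate_cohort(cohort_spec(loc, noise_range = c(1, 2000)),
                               pools), "noise_range")
  expect_error(cohort_spec(loc, noise_range = c(5, 1)), "noise_range")
})
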