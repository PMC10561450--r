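test_that("dereplication groups exact duplicates and conserves mass", {
  seqs <- c("ACGT", "ACGT", "AAGT", "ACGT", "AAGT")
  recs <- dereplicate(seqs)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$count, c(3L, 2L))
  expect_identical(sum(recs$count), length(seqs))
  # hand grouping: 3 distinct strings with counts 2,2,1, first-seen order on ties
  recs2 <- dereplicate(c("AA", "CC", "AA", "GG", "CC"))
  expect_identical(recs2$count, c(2L, 2L, 1L))
  expect_identical(recs2$sequence, c("AA", "CC", "GG"))
  # degenerate: all identical
  recs3 <- dereplicate(rep("TTTT", 7))
  expect_identical(nrow(recs3), 1L)
  expect_identical(recs3$count, 7L)
  expect_error(dereplicate(c("AC", "ACG")), "aligned")
})

test_that("dereplication conserves mass on the fixture 16S pool", {
  pool <- generate_16s_pool(seed = 42)
  recs <- dereplicate(pool$seqs)
  expect_identical(sum(recs$count), nrow(pool$seqs))
  expect_identical(nrow(pool$seqs), 265L)  # 222 CZ + 43 ALG
})

test_that("motif typing reads the two configured positions", {
  pool <- generate_16s_pool(seed = 42)
  mp <- pool$motif_positions
  recs <- dereplicate(pool$seqs)
  labels <- vapply(recs$sequence, type_haplotype, "", motif_positions = mp)
  expect_identical(sum(labels == "AG"), 7L)
  expect_identical(sum(labels == "CT"), 28L)
  expect_identical(sum(labels == "AT"), 1L)
  # ambiguity at a motif position -> OTHER with a warning
  s <- recs$sequence[1]
  substr(s, mp[1], mp[1]) <- "N"
  expect_warning(lab <- type_haplotype(s, mp), "OTHER")
  expect_identical(lab, "OTHER")
  expect_error(type_haplotype("ACGT", c(2L, 10L)), "cover")
})

test_that("16S haplotype pool respects uniqueness and the identity band", {
  pool <- generate_16s_pool(seed = 42)
  recs <- dereplicate(pool$seqs)
  expect_identical(nrow(recs), 36L)
  stats <- pairwise_identity(recs)
  expect_gte(stats$range["min"], 96.02)
  expect_lte(stats$range["max"], 99.73)
  # origin split of unique haplotypes: 26 CZ, 10 ALG, none shared
  expect_identical(sum(recs$origins == "CZ"), 26L)
  expect_identical(sum(recs$origins == "ALG"), 10L)
})

test_that("percent identity follows the pairwise-deletion arithmetic", {
  expect_identical(pairwise_identity(c("ACGT", "ACGT"))$range[["min"]], 100)
  expect_identical(pairwise_identity(c("ACGT", "ACGA"))$range[["min"]], 75)
  # gap/N columns drop out of numerator and denominator
  m <- pairwise_identity_matrix(c("AC-TN", "ACGTA"))
  expect_identical(m[1, 2], 100)
  expect_identical(pairwise_identity("ACGT")$range, numeric(0))
})

test_that("identity matrix agrees with brute-force recomputation and is symmetric", {
  set.seed(77)
  seqs <- vapply(1:10, function(i) random_seq(60), "")
  m <- pairwise_identity_matrix(seqs)
  expect_identical(m, t(m))
  expect_true(all(m >= 0 & m <= 100))
  expect_identical(unname(diag(m)), rep(100, 10))
  for (i in 1:9) for (j in (i + 1):10) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    expect_equal(m[i, j], 100 * mean(a == b))
  }
})

test_that("nearest-reference assignment: exact hit, tie, and IUPAC intersection", {
  refs <- marker_set(c("r1", "r2"), c("ACGTACGT", "TGCATGCA"), marker = "S16")
  pan <- reference_panel(refs, c("A", "B"))
  hit <- assign_by_nearest_reference("ACGTACGT", pan)
  expect_identical(hit$label, "A")
  expect_identical(hit$p_distance, 0)
  eq <- reference_panel(marker_set(c("e1", "e2"), c("AAAA", "CCCC"),
                                   marker = "S16"), c("A", "B"))
  tie <- assign_by_nearest_reference("AACC", eq)
  expect_identical(tie$label, "UNASSIGNED")
  # R intersects both A and G: distance to r1 stays 0
  amb <- assign_by_nearest_reference("RCGTACGT", pan)
  expect_identical(amb$p_distance, 0)
  expect_error(assign_by_nearest_reference("ACG", pan), "length")
})

test_that("marker discrimination ordering: TROSPA > ITS2 >= COI > 16S ~ CALR ~ 0", {
  pools <- fixture_pools()
  mk <- default_marker_pools(seed = 42)
  margin_spread <- function(pool_pair) {
    pan <- pool_reference_panel(pool_pair)
    if (inherits(pool_pair$ric, "allele_pool")) {
      queries <- c(pool_alignment(pool_pair$ric)$sequence,
                   pool_alignment(pool_pair$ino)$sequence)
    } else {
      queries <- c(pool_pair$ric$sequence, pool_pair$ino$sequence)
    }
    mean(vapply(queries, function(q)
      assign_by_nearest_reference(q, pan)$margin, numeric(1)))
  }
  m_tro <- margin_spread(pools)
  m_its <- margin_spread(mk$ITS2)
  m_coi <- margin_spread(mk$COI)
  m_16s <- margin_spread(mk$S16)
  m_cal <- margin_spread(mk$CALR)
  expect_gt(m_tro, m_its)
  expect_gte(m_its, m_coi)
  expect_gt(m_coi, m_16s * 5)      # mitochondrial margin collapses
  expect_lt(abs(m_16s), 0.005)
  expect_lt(abs(m_cal), 0.005)
})
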