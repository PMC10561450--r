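test_that("diagnostic columns are exactly the fixed, unambiguous, gap-free differences", {
  # 2 planted fixed differences (cols 3 and 7), 1 within-species polymorphic
  # column (col 5), plus an ambiguity column and a gap column to be excluded
  a <- c("AATAAAAANA", "AATACAAANA")
  b <- c("AACAAAGA-A", "AACACAGA-A")
  tab <- find_diagnostic_snps(a, b)
  expect_identical(tab$position, naive_diag_cols(a, b))
  expect_identical(tab$position, c(3L, 7L))
  expect_identical(tab$allele_A, c("T", "A"))
  expect_identical(tab$allele_B, c("C", "G"))
})

test_that("identical alignments yield an empty table; malformed input errors", {
  a <- c("ACGT", "ACGT")
  expect_identical(nrow(find_diagnostic_snps(a, a)), 0L)
  expect_error(find_diagnostic_snps(c("ACGT", "ACG"), a), "aligned")
  expect_error(find_diagnostic_snps(character(0), a), "empty")
})

test_that("discovery agrees with the column-scan oracle on random small alignments", {
  set.seed(404)
  for (i in 1:100) {
    len <- sample(20:40, 1)
    base <- strsplit(random_seq(len), "")[[1]]
    other <- base
    n_fix <- sample(0:4, 1)
    fix <- if (n_fix) sample(len, n_fix) else integer(0)
    for (p in fix) other[p] <- sample(setdiff(c("A", "C", "G", "T"), other[p]), 1)
    jitter <- function(chars) {
      hit <- sample(setdiff(seq_len(len), fix), sample(0:2, 1))
      for (p in hit) chars[p] <- sample(c("A", "C", "G", "T"), 1)
      paste(chars, collapse = "")
    }
    a <- vapply(1:3, function(i) jitter(base), "")
    b <- vapply(1:3, function(i) jitter(other), "")
    expect_identical(find_diagnostic_snps(a, b)$position, naive_diag_cols(a, b))
  }
})

test_that("the similarity threshold is a strict >= boundary", {
  mk <- function(ratio) {
    manual_trace(10, het = data.frame(position = 5, secondary = "G",
                                      ratio = ratio), primary_base = "A")
  }
  s <- peak_call_settings(similarity_threshold = 0.30)
  expect_identical(nrow(detect_double_peaks(mk(0.29), s)), 0L)
  expect_identical(detect_double_peaks(mk(0.31), s)$position, 5L)
  expect_identical(detect_double_peaks(mk(0.30), s)$position, 5L)  # >= includes 0.30
  expect_identical(detect_double_peaks(mk(0.31), s)$code, "R")
})

test_that("raising similarity to 1.0 silences every unequal-height double peak", {
  pools <- fixture_pools()
  tr <- emulate_trace(c(pools$ric$reference$sequence,
                        pools$ino$reference$sequence), seed = 6)
  s <- peak_call_settings(similarity_threshold = 1.0)
  expect_identical(nrow(detect_double_peaks(tr, s)), 0L)
})

test_that("both-strand confirmation drops strand-discordant positions", {
  tr <- manual_trace(10, het = data.frame(position = 4, secondary = "C",
                                          ratio = 0.8), primary_base = "A")
  # corrupt the reverse strand: secondary channel on a different base pair
  # (T primary, A secondary reads as A/T on the plus strand, not A/C)
  tr$reverse[4, ] <- c(800, 20, 20, 1000)
  expect_message(pk <- detect_double_peaks(tr), "disagree")
  expect_identical(nrow(pk), 0L)
  # single-strand mode accepts the forward call
  s1 <- peak_call_settings(require_both_strands = FALSE)
  expect_identical(detect_double_peaks(tr, s1)$position, 4L)
})

test_that("consensus carries IUPAC codes exactly at the heterozygous positions", {
  pools <- fixture_pools()
  tab <- fixture_table()
  ric <- pools$ric$reference$sequence
  ino <- pools$ino$reference$sequence
  cons <- consensus_with_ambiguities(emulate_trace(c(ric, ino), seed = 8))
  cc <- strsplit(cons, "")[[1]]
  rc <- strsplit(ric, "")[[1]]; ic <- strsplit(ino, "")[[1]]
  expect_identical(which(!cc %in% c("A", "C", "G", "T")), tab$position)
  for (p in tab$position) {
    expect_setequal(expand_iupac(cc[p]), c(rc[p], ic[p]))
  }
  # homozygous trace: consensus equals the underlying allele
  expect_identical(consensus_with_ambiguities(emulate_trace(c(ric, ric), seed = 9)),
                   ric)
})

test_that("species calls tolerate noise and flag hybrids", {
  pools <- fixture_pools()
  tab <- fixture_table()
  ric <- pools$ric$reference$sequence
  ino <- pools$ino$reference$sequence
  nonpanel <- setdiff(seq_len(nchar(ric)), tab$position)
  set.seed(31)
  cl <- call_sample(emulate_trace(c(ric, ric),
                                  noise_positions = sample(nonpanel, 7)), tab)
  expect_identical(cl$verdict, "RIC")
  expect_identical(cl$n_diagnostic_het, 0L)
  expect_identical(cl$n_offtarget_het, 7L)

  cl2 <- call_sample(emulate_trace(c(ino, ino),
                                   noise_positions = sample(nonpanel, 15)), tab)
  expect_identical(cl2$verdict, "INO")

  cl3 <- call_sample(emulate_trace(c(ric, ino),
                                   noise_positions = sample(nonpanel, 6)), tab)
  expect_identical(cl3$verdict, "HYBRID")
  expect_identical(cl3$n_diagnostic_het, 23L)
  expect_identical(length(cl3$double_peak_positions), 29L)
  expect_identical(cl3$n_diagnostic_het + cl3$n_offtarget_het,
                   length(cl3$double_peak_positions))
})

test_that("uninformative or excessive-noise samples are INDETERMINATE", {
  tab <- fixture_table()
  expect_identical(call_sample(strrep("N", 670), tab)$verdict, "INDETERMINATE")
  # many off-panel peaks without a hybrid signature
  pools <- fixture_pools()
  ric <- pools$ric$reference$sequence
  nonpanel <- setdiff(seq_len(nchar(ric)), tab$position)
  set.seed(32)
  cl <- call_sample(emulate_trace(c(ric, ric),
                                  noise_positions = sample(nonpanel, 20)), tab)
  expect_identical(cl$verdict, "INDETERMINATE")
  expect_error(call_sample("ACGT", tab), "coverage")
  expect_error(call_sample(strrep("N", 670), tab[0, ]), "empty")
})

test_that("phasing assigns complementary species alleles and inverts by merging", {
  pools <- fixture_pools()
  tab <- fixture_table()
  cons <- consensus_with_ambiguities(
    emulate_trace(c(pools$ric$reference$sequence, pools$ino$reference$sequence),
                  noise_positions = c(10L, 500L), seed = 12))
  hp <- phase_hybrid(cons, tab, sample_id = "441M")
  h1 <- strsplit(hp$haplotype_1, "")[[1]]
  h2 <- strsplit(hp$haplotype_2, "")[[1]]
  expect_identical(h1[tab$position], tab$allele_A)
  expect_identical(h2[tab$position], tab$allele_B)
  expect_false(any(!h1 %in% c("A", "C", "G", "T")))
  expect_setequal(hp$unphased_positions, c(10L, 500L))
  # merge-invert: IUPAC union reproduces the consensus at panel positions
  merged <- strsplit(iupac_union(hp$haplotype_1, hp$haplotype_2), "")[[1]]
  expect_identical(merged[tab$position], strsplit(cons, "")[[1]][tab$position])
  # nearest-reference places the two haplotypes on opposite species
  pan <- pool_reference_panel(pools)
  a1 <- assign_by_nearest_reference(hp$haplotype_1, pan)
  a2 <- assign_by_nearest_reference(hp$haplotype_2, pan)
  expect_identical(c(a1$label, a2$label), c("A", "B"))
  expect_gt(a1$margin, 0); expect_gt(a2$margin, 0)
})

test_that("phasing rejects unphaseable input", {
  tab <- fixture_table()
  pools <- fixture_pools()
  ric <- pools$ric$reference$sequence
  expect_error(phase_hybrid(ric, tab), "no ambiguity")
  # species-inconsistent pair at a panel position
  chars <- strsplit(ric, "")[[1]]
  bad_pair <- setdiff(c("A", "C", "G", "T"),
                      c(tab$allele_A[1], tab$allele_B[1]))
  chars[tab$position[1]] <- compress_iupac(bad_pair)
  expect_error(phase_hybrid(paste(chars, collapse = ""), tab),
               paste0("position ", tab$position[1]))
})

test_that("shrinking the panel never flips a hybrid call until coverage collapses", {
  pools <- fixture_pools()
  tab <- fixture_table()
  tr <- emulate_trace(c(pools$ric$reference$sequence,
                        pools$ino$reference$sequence), seed = 13)
  for (keep in c(23, 18, 12, 6, 2)) {
    sub <- tab[seq_len(keep), , drop = FALSE]
    class(sub) <- class(tab)
    v <- call_sample(tr, sub)$verdict
    expect_identical(v, "HYBRID")  # matched fraction stays 1.0 on the sub-panel
  }
})
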