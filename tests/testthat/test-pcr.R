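test_that("a primer equal to a template substring gives one exact site", {
  set.seed(11)
  tpl <- random_seq(200)
  p <- primer("p", substr(tpl, 61, 79), max_mismatches = 0L)
  sites <- find_primer_sites(tpl, p)
  plus <- sites[sites$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$start, 61L)
  expect_identical(plus$end, 79L)
  expect_identical(plus$mismatches, 0L)
})

test_that("one internal mismatch is tolerated while the 3' anchor is exact", {
  set.seed(12)
  tpl <- random_seq(120)
  win <- substr(tpl, 41, 59)
  chars <- strsplit(win, "")[[1]]
  chars[8] <- setdiff(c("A", "C", "G", "T"), chars[8])[1]  # outside anchor
  p <- primer("p", paste(chars, collapse = ""), max_mismatches = 1L)
  sites <- find_primer_sites(tpl, p)
  hit <- sites[sites$strand == "+" & sites$start == 41L, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$mismatches, 1L)

  # the same substitution inside the anchor kills the site
  chars2 <- strsplit(win, "")[[1]]
  chars2[17] <- setdiff(c("A", "C", "G", "T"), chars2[17])[1]
  p2 <- primer("p2", paste(chars2, collapse = ""), max_mismatches = 2L)
  sites2 <- find_primer_sites(tpl, p2)
  expect_false(any(sites2$strand == "+" & sites2$start == 41L))
})

test_that("degenerate primer bases match their expansions", {
  tpl <- "TTTTTGTAAACATCGGCCTAATGGTTTTT"
  p <- primer("deg", "GTAAACATCGGCCTRATGG")  # R matches the A
  sites <- find_primer_sites(tpl, p)
  expect_identical(sites$mismatches[sites$strand == "+"], 0L)
})

test_that("scanner agrees with the exhaustive sliding-window oracle", {
  set.seed(202)
  for (rep in 1:120) {
    n <- sample(150:400, 1)
    tpl <- random_seq(n)
    # half the time, plant a mutated copy of a window to create near-sites
    p_seq <- if (rep %% 2 == 0) {
      s <- sample(n - 20, 1)
      w <- strsplit(substr(tpl, s, s + 18), "")[[1]]
      flip <- sample(19, sample(0:3, 1))
      for (j in flip) w[j] <- sample(setdiff(c("A", "C", "G", "T"), w[j]), 1)
      paste(w, collapse = "")
    } else random_seq(19)
    p <- primer("p", p_seq, max_mismatches = 2L)
    got <- find_primer_sites(tpl, p)
    want <- naive_sites(tpl, p)
    expect_identical(got[, c("strand", "start", "end", "mismatches")], want)
  }
})

test_that("amplicon lengths match hand coordinate arithmetic on a toy template", {
  # 50 bp template, forward footprint at 3..17, reverse footprint at 31..46
  set.seed(33)
  tpl_chars <- strsplit(random_seq(50), "")[[1]]
  fwd <- primer("f", "ACGTACGTACGTACG", max_mismatches = 0L)
  rev <- primer("r", "TTGGCCAATTGGCCAA", max_mismatches = 0L)
  tpl_chars[3:17] <- strsplit(fwd$sequence, "")[[1]]
  tpl_chars[31:46] <- strsplit(revcomp(rev$sequence), "")[[1]]
  tpl <- paste(tpl_chars, collapse = "")
  amps <- predict_amplicons(tpl, fwd, rev)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$length, 46L - 3L + 1L)   # 5'-to-5' inclusive
})

test_that("strand symmetry: reverse-complementing the template and swapping the pair preserves lengths", {
  pools <- fixture_pools()
  assay <- trospa_assay()
  tpl <- pools$ric$reference$sequence
  fwdlen <- predict_amplicons(tpl, assay$fwd_A, assay$rev_A)$length
  swapped <- predict_amplicons(revcomp(tpl), assay$rev_A, assay$fwd_A)$length
  expect_identical(sort(fwdlen), sort(swapped))
})

test_that("fixture alleles amplify at the panel sizes with their own pair only", {
  pools <- fixture_pools()
  assay <- trospa_assay()
  ric <- pools$ric$reference$sequence
  ino <- pools$ino$reference$sequence
  a <- predict_amplicons(ric, assay$fwd_A, assay$rev_A)
  expect_identical(a$length, 362L)
  expect_identical(nrow(predict_amplicons(ino, assay$fwd_A, assay$rev_A)), 0L)
  b <- predict_amplicons(ino, assay$fwd_B, assay$rev_B)
  expect_identical(b$length, 233L)
  expect_identical(nrow(predict_amplicons(ric, assay$fwd_B, assay$rev_B)), 0L)
})

test_that("gel verdicts follow the band pattern", {
  pools <- fixture_pools()
  assay <- trospa_assay()
  ric <- pools$ric$reference$sequence
  ino <- pools$ino$reference$sequence
  expect_identical(multiplex_gel(c(ric, ric), assay)$verdict, "SPECIES_A")
  expect_identical(multiplex_gel(c(ino, ino), assay)$verdict, "SPECIES_B")
  g <- multiplex_gel(c(ric, ino), assay)
  expect_identical(g$verdict, "HYBRID")
  expect_setequal(g$bands, c("A", "B"))
  set.seed(5)
  outgroup <- random_seq(670)
  expect_identical(multiplex_gel(c(outgroup, outgroup), assay)$verdict, "NONE")
})

test_that("primer and assay validation catch malformed inputs", {
  expect_error(primer("short", "ACGTACGT"), "15")
  expect_error(multiplex_assay(primer("f", strrep("ACGT", 5)),
                               primer("r", strrep("ACGT", 5)), 240,
                               primer("f2", strrep("ACGT", 5)),
                               primer("r2", strrep("ACGT", 5)), 233),
               "distinguishable")
  p <- primer("p", strrep("ACGT", 5))
  expect_identical(nrow(find_primer_sites("ACGTACGT", p)), 0L)
})
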