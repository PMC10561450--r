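# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and memoised here.

.fix_env <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (!exists(key, envir = .fix_env)) assign(key, builder(), envir = .fix_env)
  get(key, envir = .fix_env)
}

fixture_pools <- function() .memo("pools", function() {
  generate_allele_pools(seed = 42)
})

fixture_table <- function() .memo("table", function() {
  p <- fixture_pools()
  find_diagnostic_snps(pool_alignment(p$ric), pool_alignment(p$ino))
})

fixture_full_report <- function() .memo("full_report", function() {
  run_pipeline(default_study_config(seed = 42,
                                    outdir = file.path(tempdir(), "full_run")))
})

fixture_subset_report <- function() .memo("subset_report", function() {
  run_pipeline(default_study_config(seed = 42,
                                    outdir = file.path(tempdir(), "subset_run"),
                                    sequence_subset = TRUE))
})

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# independent oracle: naive character-by-character primer scan on both strands
naive_sites <- function(template, primer) {
  tc <- strsplit(toupper(template), "")[[1]]
  scan_one <- function(pseq, strand, anchor_left) {
    pc <- strsplit(pseq, "")[[1]]
    m <- length(pc)
    hits <- list()
    for (s in seq_len(max(0L, length(tc) - m + 1L))) {
      mm <- 0L; anchor_ok <- TRUE
      for (j in seq_len(m)) {
        ok <- length(intersect(expand_iupac(pc[j]),
                               expand_iupac(tc[s + j - 1L]))) > 0
        if (!ok) {
          mm <- mm + 1L
          in_anchor <- if (anchor_left) j <= primer$three_prime_anchor
                       else j > m - primer$three_prime_anchor
          if (in_anchor) anchor_ok <- FALSE
        }
      }
      if (anchor_ok && mm <= primer$max_mismatches) {
        hits[[length(hits) + 1L]] <- data.frame(
          strand = strand, start = s, end = s + m - 1L, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  fwd <- scan_one(primer$sequence, "+", anchor_left = FALSE)
  rev <- scan_one(revcomp(primer$sequence), "-", anchor_left = TRUE)
  out <- rbind(fwd, rev)
  if (is.null(out)) {
    return(data.frame(strand = character(), start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent oracle: exhaustive fixed-difference column enumeration
naive_diag_cols <- function(seqs_a, seqs_b) {
  A <- do.call(rbind, strsplit(toupper(seqs_a), ""))
  B <- do.call(rbind, strsplit(toupper(seqs_b), ""))
  plain <- c("A", "C", "G", "T")
  hits <- integer(0)
  for (p in seq_len(ncol(A))) {
    ca <- unique(A[, p]); cb <- unique(B[, p])
    if (length(ca) == 1L && length(cb) == 1L && ca != cb &&
        ca %in% plain && cb %in% plain) {
      hits <- c(hits, p)
    }
  }
  hits
}

# build a two-strand chromatogram directly from explicit channel heights;
# `spec` rows: position, primary base, optional secondary base + ratio
manual_trace <- function(len, het = NULL, primary_base = "A",
                         primary_h = 1000, baseline = 20, sample_id = "manual") {
  mk <- function(prim_of, sec_of) {
    h <- matrix(baseline, nrow = len, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    for (p in seq_len(len)) {
      h[p, prim_of(p)] <- primary_h
      s <- sec_of(p)
      if (!is.null(s)) h[p, s$base] <- s$ratio * primary_h
    }
    h
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  het_at <- function(p) {
    if (is.null(het)) return(NULL)
    row <- het[het$position == p, ]
    if (nrow(row)) list(base = row$secondary[1], ratio = row$ratio[1]) else NULL
  }
  fwd <- mk(function(p) primary_base, het_at)
  rev <- mk(function(p) comp[[primary_base]], function(p) {
    s <- het_at(p)
    if (is.null(s)) NULL else list(base = comp[[s$base]], ratio = s$ratio)
  })
  structure(list(sample_id = sample_id, length = len, forward = fwd,
                 reverse = rev), class = "chromatogram")
}
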