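---
title: "Methods: in-silico multiplex PCR, double-peak diagnostics, and hybrid phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico multiplex PCR, double-peak diagnostics, and hybrid phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickhybrid)
```

## The problem

*Ixodes ricinus* and *Ixodes inopinatus* are sibling tick taxa that
morphology and the standard mitochondrial barcodes (16S rDNA, *COI*) cannot
reliably separate. The intron of the nuclear *TROSPA* gene does separate
them: it carries a panel of positions at which every *I. ricinus* allele has
one fixed base and every *I. inopinatus* allele a different fixed base. A
diploid individual carrying one allele of each species — a hybrid — is
heterozygous at every panel position at once, which is visible both as two
bands on a multiplex PCR gel and as a long run of double peaks in a Sanger
chromatogram. This package implements that entire inference chain over
synthetic data with known truth, so each stage is a parameter-recovery
experiment.

## Models and procedures

### In-silico PCR

A primer binds a template window when at most `max_mismatches` positions are
incompatible (IUPAC base sets that do not intersect) *and* the
`three_prime_anchor` terminal bases match exactly — the polymerase cannot
extend a mismatched 3' end. Defaults are 2 mismatches and a 5-base anchor,
ordinary primer-specificity practice; both are arguments of `primer()`. The
scanner works on a bitmask encoding (A=1, C=2, G=4, T=8; ambiguity codes OR
their bases) so a window mismatch count is a handful of vectorised AND
operations; an exhaustive character-by-character scan serves as the oracle in
the test suite, never as the implementation.

Product length is counted 5'-to-5' inclusive of both primer footprints, the
convention in which assay product sizes are quoted (362 bp and 233 bp for
the packaged panel). A band is reported when an amplicon falls within
`size_tolerance` (default 10 bp, a gel-resolution proxy) of the expected
size; one band of each pair gives the verdicts `SPECIES_A` / `SPECIES_B`,
both give `HYBRID`, neither gives `NONE`. Annealing temperatures in the
panel file are metadata and are never used computationally.

### Double-peak detection

The trace model is a per-position, per-strand table of four channel heights
— sufficient for the detector's contract without modelling continuous
electropherograms. A position is a double peak when, on each required
strand:

* the secondary channel is at least `similarity_threshold` × the primary
  channel (default 0.30, compared with `>=`), and
* the primary channel is at least `height_threshold` × the local
  running-maximum signal (default 0.50, window of 21 positions).

The thresholds are deliberately the simplest monotone reading of the "peak
similarity 30% / peak detection height 50%" settings familiar from
chromatogram software; they are exposed in `peak_call_settings()`. Reverse-
strand calls are complemented to plus-strand orientation, and a position
where the strands disagree on the base pair is dropped with a note.
`consensus_with_ambiguities()` then writes the IUPAC code of the pair at
each detected position (A/G → R, and so on).

### Species/hybrid calling

Against a diagnostic table of `p` positions, a sample is `HYBRID` when at
least `hybrid_min_fraction` of panel positions are heterozygous *and* every
on-panel pair is exactly the two species alleles. The default 0.85 (≥ 20/23)
tolerates single-position dropouts; setting it to 1.0 reproduces a strict
all-23 rule. Otherwise homozygous panel positions vote A vs B by majority;
a tie or panel coverage below 50% yields `INDETERMINATE` rather than a
silent default. A non-hybrid sample whose trace shows more than
`max_noise_het` double peaks (default 15, the upper end of the noise range
the generator plants) is also `INDETERMINATE`: such a sample is outside both
calibrated regimes, and deciding it would be guesswork.

### Phasing ("in-silico cloning")

A hybrid consensus splits into two haplotypes: haplotype 1 takes the
species-A allele and haplotype 2 the species-B allele at every heterozygous
panel position; a panel position observed homozygous keeps its observed base
in both haplotypes (so that re-merging the pair with a positionwise IUPAC
union reproduces the consensus — a tested inversion). Off-panel heterozygous
positions cannot be phased from a single locus without linkage information;
both haplotypes receive the alphabetically first base and the position is
flagged in `unphased_positions`. A species-inconsistent base pair at a panel
position is an error naming the position, not a silent skip.

### Nearest-reference assignment

Tree building is out of scope; clade-placement claims are tested as distance
properties instead. `assign_by_nearest_reference()` computes the mean
p-distance (ambiguity codes match when base sets intersect; gap columns
excluded pairwise) from a query to each species' labelled references and
returns the closest label plus a margin (second-best minus best). Mean
distance rather than single nearest neighbour is used for robustness to one
aberrant reference. On the fixture, TROSPA margins exceed the within-species
spread while 16S and calreticulin margins collapse toward zero — the
qualitative ranking the markers are known for.

### 16S typing

`dereplicate()` groups exact-matching aligned sequences into haplotype
records; `type_haplotype()` reads the two configured motif positions and
returns AG, CT, AT or OTHER (ambiguity or gap at a motif position is OTHER
with a warning). Pairwise identity uses pairwise deletion of gap/N columns.

## The synthetic-data generator

The generator's defaults *are* the study conditions; they are set once and
are not tuning knobs.

* **Allele pools** (`generate_allele_pools()`): a 670 bp region, panel of
  23, five within-species variant alleles per species at a per-site
  substitution rate of 0.005, variants polymorphic only away from the panel.
  The four primer footprints are embedded in the region, and one panel SNP
  sits in the 3' anchor of each footprint *on the opposite species' allele*.
  This single construction makes three contracted facts simultaneously true:
  the references differ at exactly 23 positions; each species amplifies only
  with its own pair; and panel discovery on the alignments returns exactly
  those 23 columns. A bounded retry re-draws the random backbone in the rare
  event a spurious primer site arises elsewhere.
* **Cohort** (`generate_cohort()`): the four-locality composition
  (321 / 43 / 10 over 374, with the printed per-sex layout) or the
  140-sample sequenced subset (112 / 18 / 10; the published per-class
  arithmetic is off by one between 141 sequenced and 140 categorised, and
  the 13 / 117 / 10 categorisation is taken as authoritative). Non-hybrids
  are homozygous for one pool allele; their traces carry noise double peaks
  at random non-diagnostic positions, 1–15 per sample, with an exact
  `zero_noise_fraction` share (13/130 in subset mode) carrying none.
  Hybrids carry the two reference alleles plus extras up to a total drawn
  from 25–32. Making the zero-noise share exact rather than binomial is what
  lets a fixed composition be recovered exactly at any seed.
* **16S pool** (`generate_16s_pool()`): 36 unique haplotypes
  (26 CZ / 10 ALG; 7 AG, 28 CT, 1 AT at positions 101 and 153 of a 455 bp
  fragment — the motif coordinates are a fixture convention, as the real
  ones are defined in prior literature, not here). Each haplotype owns 2–7
  private substitutions on a shared backbone, so any two haplotypes differ
  at 4–16 sites: inside the 96.02–99.73% identity band and never identical.
  Members (222 CZ + 43 ALG) are distributed one-per-haplotype plus a
  multinomial remainder.
* **Secondary markers** (`generate_marker_pool()`): ITS2 with 8 and *COI*
  with 5 fixed differences (both separate the species), 16S and a
  calreticulin-like fragment with none (neither does) — the negative
  controls. Hybrid individuals would carry pure ricinus-type ITS2 under the
  concerted-evolution reading adopted here.

What the generator does **not** emulate: indel polymorphism, quality-score
structure, base-caller artefacts, primer-dimer or thermodynamic effects, and
backcross generations (an F1 and an introgressed individual look identical
to single-locus logic). Passing tests therefore demonstrate the inference
chain's internal correctness and calibration on clean double-peak signal,
not robustness to raw-trace pathologies.

## Numerical and design choices

* Coordinates are 1-based and closed everywhere a user sees them (IRanges
  convention); positions in diagnostic tables are relative to the named
  synthetic reference, and inputs are required pre-aligned to it (alignment
  itself is out of scope).
* The similarity threshold is compared with `>=`, so a secondary peak at
  exactly 30% of the primary is reported.
* Sequences are uppercased on ingest; lowercase is treated as soft-mask.
  Gaps are legal in stored alignments, illegal in primers.
* Ambiguity codes in deposited-style sequences are written as full IUPAC
  rather than N, preserving the base pair for phasing.
* Ties — species votes, nearest-reference distances — always produce an
  explicit `INDETERMINATE`/`UNASSIGNED`, never a default winner.
* Determinism: every generator takes a seed and is a pure function of its
  arguments; pipeline runs with the same config produce byte-identical
  artifacts.

## Problem sizes

The shipped experiments are desk-scale by design: a 374-individual cohort
with 670 bp two-strand traces, a 140-trace subset, 36 × 455 bp haplotypes,
and property tests over ~120 random templates of 150–400 bp for the
scanner-vs-oracle check and 100 random small alignments for the
discovery-vs-enumeration check. The full suite and the acceptance script
each run in a couple of minutes on one CPU.

## Known limitations

Single-locus phasing assigns off-panel heterozygous sites arbitrarily (and
says so); the hybrid caller cannot distinguish F1 hybrids from later
backcrosses; the in-silico PCR has no thermodynamic model, so a primer with
a compatible-but-weak duplex is treated as binding; and the 16S identity
band is enforced over haplotypes, not over raw reads. These mirror the
limits of the wet-lab design the package emulates rather than shortcuts in
the implementation.
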