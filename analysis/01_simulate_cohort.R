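#!/usr/bin/env Rscript
# Build the synthetic study fixture: the two TROSPA allele pools with their
# 23-position diagnostic panel, and the 374-tick cohort laid out over four
# localities (three CZ, one ALG) with 321 species-A, 43 species-B and 10
# hybrid individuals. Everything downstream is a pure function of the seed,
# so later scripts regenerate the cohort in memory instead of re-reading the
# (large) trace files.

library(tickhybrid)
seed <- 42L
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

pools <- generate_allele_pools(seed = seed)
cat("Allele pools: references differ at", nrow(pools$table), "positions\n")
write_tsv(as.data.frame(pools$table), "results/analysis/planted_panel.tsv")
write_fasta(rbind(pool_alignment(pools$ric), pool_alignment(pools$ino)),
            "results/analysis/trospa_pools.fasta")

cohort <- generate_cohort(study_cohort_spec(seed = seed), pools)
print(cohort)
write_fasta(cohort_trospa_alleles(cohort), "results/analysis/cohort_trospa.fasta")
truth <- cohort$individuals[, c("sample_id", "locality", "origin", "sex",
                                "true_class", "n_planted_peaks")]
write_tsv(truth, "results/analysis/cohort_truth.tsv")
cat("Wrote", nrow(truth), "individuals; truth labels kept only for validation.\n")
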