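Package: tickhybrid
Title: In Silico Multiplex PCR and Hybrid Detection for the Ixodes
    ricinus/inopinatus Complex
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to distinguish the near-identical sibling ticks Ixodes
    ricinus and Ixodes inopinatus and to detect their hybrids from Sanger-style
    data. Implements in silico multiplex PCR on the TROSPA intron (primer-site
    search with 3'-anchor semantics, amplicon prediction, gel-pattern calling),
    discovery of fixed diagnostic SNP panels from species-labelled alignments,
    both-strand double-peak heterozygote detection on chromatogram-like traces,
    species/hybrid calling, phasing of hybrid consensi into species-assignable
    haplotypes (in silico cloning), and 16S rDNA haplotype dereplication and
    motif typing with p-distance nearest-reference assignment. A synthetic
    cohort generator emulates the statistical structure of a two-species tick
    survey so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
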