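Package: tmaur
Title: Rare-Variant Prioritization and Choline-Challenge Analysis for
    Trimethylaminuria
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying impaired trimethylamine (TMA) metabolism
    (trimethylaminuria, TMAU). Classifies subjects from choline-challenge
    urine collections using the TMAO fraction of total TMA species, reads
    multi-sample exome VCF genotypes into a zygosity matrix, and runs a
    multi-branch rare-variant prioritization cascade (cohort homozygote
    presence, SIFT/PolyPhen-2 deleteriousness, oxidoreductase gene-set
    membership, minor-allele-frequency rarity, and cross-subject sharing).
    Also provides known-variant catalog lookup, seed-gene interactome
    expansion over scored protein-interaction edge lists, orthogonal
    genotyping concordance, per-subject reporting, and a synthetic cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
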