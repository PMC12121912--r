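Package: sdrscan
Title: Sex Chromosome and Sex-Determination Region Inference from
    Male-Female Sequencing Contrasts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies the heterogametic system (XY vs ZW) and delineates the
    sex-determination region (SDR) of a genome from male/female sequencing
    contrasts: windowed Fst (Weir-Cockerham, Hudson, and pool-seq estimators),
    per-sex nucleotide diversity, SNP density, normalized male:female depth
    ratios, and sex-specific k-mer density.  Detects and genotypes polymorphic
    X- and Y-linked chromosomal inversions from linked-read barcode sharing
    between distal windows, classifies their linkage, and predicts their
    segregation in single-pair crosses.  Quantifies early Y-chromosome
    degeneration via depth-ratio flags, fixed loss-of-function rules, and
    Nei-Gojobori (1986) dN/dS for X/Y gene pairs.  A seeded synthetic cohort
    generator emulating an XY system with population-specific inversions makes
    every stage testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    stringi,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
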