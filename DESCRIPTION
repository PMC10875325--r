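Package: mitolink
Title: Mitonuclear Linkage-Disequilibrium Analysis from Population Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects statistical associations (linkage disequilibrium) between
    mitochondrial and nuclear genome variants within a species. Mitochondrial
    variant calls are filtered against repeat- and numt-driven artifacts,
    converted into per-variant heteroplasmy phenotypes (reference-allele read
    fractions), and tested against nuclear SNPs with a kinship-aware
    variance-component mixed model (EMMAX-style generalized least squares).
    Above-threshold SNPs are clustered into association signals with lead SNPs
    and overlapping genes, and downstream contrasts are provided: windowed
    nucleotide diversity, Nei-Gojobori (1986) Ka/Ks against an outgroup, gene
    set enrichment, and replicate-consensus detection of mitochondrial C-to-U
    RNA-editing sites from RNA-seq variant calls. A synthetic-data generator
    produces structured populations, heteroplasmic read counts, repeat/numt
    genomes, and editing count data so the whole pipeline can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
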