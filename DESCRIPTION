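Package: editscape
Title: A-to-I RNA Editing Landscapes from Matched DNA and RNA Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection, classification and annotation of adenosine-to-inosine
    (A-to-I) mRNA editing sites from per-site, per-sample allele-depth tables
    together with same-individual genomic genotypes. Candidate sites are
    separated from heterozygous A/G genomic polymorphisms, per-sample edit
    frequencies are pooled into depth-weighted neural (WN) and non-neural
    (WNN) averages, and sites are classified into neural and ubiquitous
    (low/medium/high) editing classes. Edits are annotated against gene
    models for recoding versus synonymous consequences with BLOSUM62 scores,
    intersected with repeat and protein-domain tracks, and compared against
    outgroup-species genotypes to call lineage-specific edits. A seeded
    synthetic-data generator plants sites of known class so that every stage
    of the pipeline can be verified against ground truth, and reporting
    helpers produce feature-by-class cross-tabulations, edit-frequency
    histograms, tissue correlation clusterings and per-gene editing profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
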