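Package: mitoPattern
Type: Package
Title: Somatic Mitochondrial DNA Heteroplasmy Filtering, Annotation and
    Selection Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mitochondrial genome analysis from capture-based deep
    sequencing: a read-count-level filter cascade for heteroplasmic single
    nucleotide variants (per-strand support, coverage, per-strand VAF, repeat
    masks, oxidative 8-oxoG exclusion and a strand-orientation-bias rule for
    FFPE material), somatic classification against matched controls, mtDNA
    copy-number estimation from mitochondrial-to-nuclear depth ratios, a
    circular rCRS coordinate model (control region, hypervariable segments,
    genes, OXPHOS complexes, tRNA cloverleaf elements), strand-resolved
    substitution spectra and region-normalised mutation densities including a
    replication-strand-asymmetry (DssH) standardisation across OXPHOS
    complexes, Kaplan-Meier and log-rank outcome stratification, and a
    synthetic cohort simulator with a planted-truth ledger for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, VariantAnnotation, Sequencing, Survival
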