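Package: SexLinkScan
Title: Sex-Determination System Inference and Sex-Linked InDel Marker
    Discovery from Population Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers a species' sex-determination system (male-heterogametic
    XX/XY versus female-heterogametic ZW/ZZ) from multi-sample variant calls
    and sex phenotypes, and develops PCR-resolvable sex-linked InDel markers.
    Implements GATK-style hard filtering and VCFtools-style site filtering,
    principal-component covariate selection, a per-variant general linear
    model association scan with genomic-inflation diagnostics, linkage
    disequilibrium decay and marker-sufficiency analysis, lead-SNP candidate
    windows with interval-based gene assignment, pooled zygosity segregation
    classification, gel band-pattern prediction for InDel markers, a
    simplified gonadal differential-expression stage with GWAS overlap, and
    a forward simulator of sex-linked populations with configurable
    recombination decay, genotyping error, and negative-binomial expression
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
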