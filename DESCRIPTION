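Package: polybrix
Title: Presence/Absence Allele-Trait Association for Autopolyploid Berry Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping of soluble solids content (SSC, degrees Brix)
    in mixed-ploidy clonal germplasm such as cultivated blackberry. Builds
    locus genotype tables from multi-sample VCFs with depth-based missingness,
    encodes dominant (presence/absence) locus-allele markers, screens them with
    Welch's t-test and Benjamini-Hochberg correction, infers population
    structure by principal components and k-means with a BIC model choice, and
    separates structure-independent trait associations with nested linear
    models. Also validates diagnostic markers per environment, designs
    KASP-style flanking consensus sequences with IUPAC ambiguity codes, audits
    sequencing-versus-assay genotype concordance, intersects cross-species
    syntenic blocks with trait QTL intervals, and performs capture-bait tiling
    arithmetic. A seeded cohort simulator with planted allele effects supports
    power and error-control studies end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
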