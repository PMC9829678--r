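Package: introtrace
Title: In Silico Introgression Mapping and Stress Phenotypics for Wheat Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects alien chromosome segments (introgressions from wild
    relatives such as Aegilops tauschii) in hexaploid wheat panels from
    windowed read-mapping coverage deviation and donor-species-specific SNP
    enrichment, calls segment zygosity, and intersects carrier segments into
    a core introgressed region. Also implements the accompanying
    stress-phenotypics layer (stress susceptibility index, broad-sense
    heritability, derived agronomic traits, elite-vs-exotic comparisons and
    allele-stacking effects) and synteny-based anchoring of candidate
    intervals onto donor assemblies, together with a synthetic panel
    generator that reproduces the statistical structure the analysis
    assumes so that every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
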