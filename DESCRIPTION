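Package: varkin
Title: Variant Prioritization and Segregation Analysis in Familial Cancer Kindreds
Version: 0.1.0
Authors@R: person("varkin", "maintainers", email = "varkin@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing germline candidate variants in extended
    families segregating a dominant cancer-susceptibility allele with
    incomplete penetrance. Implements a shared-carrier intersection and
    population/internal allele-frequency filter cascade with an auditable
    filter trace, pedigree segregation-compatibility classification under
    dominant and recessive (including pseudo-dominant) models, exact
    two-point parametric LOD scores by generalized Elston-Stewart peeling,
    tumor-versus-germline somatic subtraction with gene-panel restriction
    and second-hit scanning, bounded-length protein-protein interaction
    path search linking candidates to known susceptibility genes, and a
    gene-dropping pedigree simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
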