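Package: somaclone
Title: Somatic-Mutation Phylogenies Across Tumour and Normal Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs clonal phylogenies from multi-sample somatic
    variant read counts, as used for developmental lineage tracing of
    tumours against surrounding normal tissues. Classifies germline versus
    somatic variants with a one-sided binomial exact test and
    Benjamini-Hochberg correction, applies consistent-depth site filters,
    separates true variant presence from sequencing noise with a
    site-specific beta-binomial error model, clusters mutations across
    samples with a Dirichlet-process mixture of binomials fitted by
    collapsed Gibbs sampling, and reconciles clusters into a clone tree
    under the pigeonhole principle with per-tissue clone sizes and
    per-branch mutation burdens. Includes a synthetic read-count generator
    emulating an embryonic clone tree sampled across tissues, so the whole
    pipeline is testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
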