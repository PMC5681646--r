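Package: ssrdeconv
Title: Strain-Level Deconvolution of Mixed Yeast Populations from
    Microsatellite Meta-Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies the Saccharomyces cerevisiae strains composing a
    mixed sample from its microsatellite (SSR) meta-profile. Allele calls
    at a panel of SSR loci are encoded as presence/absence vectors and the
    sample profile is regressed on a reference collection of single-strain
    profiles with a non-negative, intercept-free L1-penalized binomial
    GLM; strains with non-zero coefficients at the cross-validated penalty
    are called present. Includes locus-level performance statistics
    (discrimination ability, average locus error, true-positive rate,
    GLM error), Cavalli-Sforza chord distances and neighbor-joining
    typing trees, recursive redundancy pruning of reference collections,
    and a seeded simulator of clonal strain collections and pooled
    meta-profiles with amplification noise for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    ape,
    phangorn,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
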