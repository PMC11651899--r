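Package: dyadmm
Title: Dyadic Multi-Membership Models for Hybrid-Zone Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying host-genetic and environmental structuring of
    multi-amplicon intestinal community data across a hybrid zone. Computes
    admixture metrics (hybrid index, expected hybrid heterozygosity) and their
    pairwise distances, applies prevalence/abundance quality filters and total
    sum scaling to amplicon sequence variant (ASV) tables, merges co-abundant
    within-genus ASVs into combined ASVs (cASVs) via Spearman co-abundance
    networks and greedy modularity clustering, builds occurrence (Jaccard) and
    abundance (Aitchison) pairwise similarity tables over all sample dyads, and
    fits Bayesian Gaussian multi-membership dyadic regressions of community
    similarity on genetic and environmental distances by an exact blocked Gibbs
    sampler. Includes a synthetic hybrid-zone generator with known ground-truth
    effects for operating-characteristic testing, and a pipeline orchestrator
    with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    biomformat
Config/testthat/edition: 3
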