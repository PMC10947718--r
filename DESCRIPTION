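Package: gillnetTools
Title: Evaluation and Redesign of Multi-Mesh Gillnet Survey Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and redesigning stratified multi-mesh
    gillnet surveys of lake fish communities. Standardizes catches over
    heterogeneous net panel geometries to numbers and biomass per unit
    effort (NPUE/BPUE), tests equivalence of net designs with two
    one-sided tests (TOST) including achieved power and required sample
    size, computes permutation community statistics (Bray-Curtis
    dissimilarity with a dummy species, principal-coordinate embedding,
    ANOSIM, PERMDISP), fits species-accumulation curves with an exact
    hypergeometric estimator, and calculates prospective net numbers from
    coefficient-of-variation precision targets (Pringle formula) and
    power-based sample sizes, with volume-proportional allocation across
    depth strata. A seeded negative-binomial catch simulator generates
    surveys with realistic overdispersion, species dominance and paired
    net deployments for testing every stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
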