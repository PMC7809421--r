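Package: hemilat
Title: Hemispheric Lateralization Analysis of Neonatal Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying left-right asymmetry of structural brain
    networks in neonatal diffusion-MRI cohorts. Builds region-by-region
    connectivity matrices from streamline summaries, splits them into
    intra-hemispheric binary networks, computes graph-theoretic measures
    (characteristic path length, global and local efficiency, clustering,
    small-worldness against degree-preserving null models, and betweenness
    centrality of fronto-limbic regions), scores per-subject hemispheric
    asymmetry, and compares asymmetry between groups with covariate-adjusted
    linear models under Benjamini-Hochberg false-discovery-rate control.
    Includes a synthetic-cohort generator with plantable hemispheric effects
    so the full pipeline can be exercised and calibrated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
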