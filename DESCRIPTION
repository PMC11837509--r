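Package: metabuffer
Title: Functional Redundancy and Buffering of Microbiome Metabolic Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how community metabolic capacity is
    buffered against phylotype loss in host-associated microbiomes. Provides
    a calibrated synthetic-community generator (taxon counts, genome
    content, pathway catalogs), sample- and phylotype-level quality filters,
    Hill-number alpha diversity, dissimilarity-based community statistics
    (NMDS, PERMANOVA with restricted permutation schemes, multivariate
    dispersion tests), a metabolic-capacity engine that partitions inferred
    pathways into per-taxon and obligately-shared classes via minimal
    pathway-set parsimony, prevalence-based pathway fate classification
    between treatment windows, and taxon-knockout simulations of functional
    redundancy.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
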