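Package: fungalassembly
Title: Community Assembly Inference for Abundant and Rare Soil Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ecological processes structuring soil fungal
    metacommunities from ASV count tables. Classifies taxa into abundant,
    rare and intermediate fractions at local and regional relative-abundance
    thresholds, estimates Levins' niche breadth and abundance-weighted
    community niche breadth, computes abundance-based null-model beta
    deviations (standardized effect sizes of Bray-Curtis beta diversity),
    fits the Sloan neutral community model, quantifies distance-decay of
    community similarity, and attributes beta-deviation variance to spatial
    and environmental predictors via multiple regression on distance
    matrices with forward selection, two-set variation partitioning,
    hierarchical partitioning and recursive path analysis. Ships a seeded
    synthetic metacommunity generator emulating a 30-site desert transect
    design (90 quadrat samples, four vegetation types, lognormal species
    abundances, Gaussian niche selection, distance-limited dispersal and
    neutral immigration) so that every inference step can be validated
    against data with known assembly processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
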