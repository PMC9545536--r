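Package: hierstab
Title: Hierarchical Partitioning of Temporal Stability Across Ecological Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions the temporal variability (coefficient of variation, CV)
    of multisite community biomass across hierarchical levels of ecological
    organization.  Local population CV is upscaled to regional community CV
    along two pathways (via local community CV with local species synchrony and
    regional community synchrony, or via regional population CV with regional
    population synchrony and regional species synchrony), for all species or
    only dominant species.  Includes alpha/beta/gamma species diversity and
    effective species richness, climate-series CV and spatial synchrony with
    the same estimators, a resampling construction of regional communities
    from disjoint site pairs, a randomized-examination significance procedure,
    piecewise path models with AICc pruning, and a synthetic multisite
    biomass/precipitation generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
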