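Package: pollscape
Title: Linking Historical Land-Cover Change to Pollinator Community Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating multi-decadal categorical land-cover change to
    change in pollinator (bee and wasp) species richness and community
    composition across a set of focal sites. Provides per-class cover-change
    and cell-adjacency (edge-habitat) metrics at the site scale and in buffer
    annuli around each site; sampling-effort-corrected richness change via
    individual-based rarefaction and Chao1-style extrapolation with a
    bootstrap bias and variance estimate; an abundance-corrected species
    composition change (SCC) index built from shared-species relative
    abundances; inverse-variance random-effects meta-regression with
    heterogeneity-accounted (VAF) statistics, constrained stepwise AICc model
    selection, a sampling-effort bias check, and a Moran's I spatial screen.
    Includes a synthetic-data generator with known ground truth so the whole
    pipeline can be exercised and validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
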