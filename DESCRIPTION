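Package: soilweb
Title: Co-Occurrence Network Tightening and Stable-Isotope Tracer
    Accounting for Soil Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing soil food-web structure along succession
    chronosequences. Builds per-stage species co-occurrence networks from
    abundance tables (Spearman rank correlation with a strong-correlation
    threshold), computes percentage connectance and group-level interaction
    strengths, and detects "network tightening" across land-abandonment
    stages, with abundance and presence-absence variants. Implements the
    companion stable-isotope bookkeeping for dual 13C/15N pulse-chase
    experiments: delta/ratio/atom-percent algebra against VPDB and air-N2
    references, standard-curve calibration (USGS40/USGS41 and related
    reference materials), excess-label computation against unlabelled
    controls, elemental-content standard curves, PLFA/NLFA biomarker pool
    aggregation, fungal-to-bacterial ratios, and root-scaled carbon-channel
    partitioning. A synthetic-data module generates community abundance
    tables with tunable block correlation and tracer experiments with known
    transfer fractions so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
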