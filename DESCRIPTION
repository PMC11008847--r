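Package: epideform
Title: Deformable-Polygon Simulation of Epithelial Apical-Basal Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-based simulation of epithelial monolayer cross-sections in
    the apical-basal (XZ) plane. Each cell cortex is a closed polyline of
    nodes evolving under overdamped explicit-Euler dynamics with an
    area-perimeter internal energy, spring-like cell-cell and cell-substrate
    adhesion, short-range repulsion, gravity, an active spreading force with
    contact inhibition, adhesion cross-talk feedback, cortical remodeling and
    planar cell division. Includes layer metrics (connection fractions,
    density, apical-to-basal surface-length ratio, shape index) that classify
    simulated layers as Immature or Intermediate, scenario runners and
    densification sweeps, and text/binary trajectory serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
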