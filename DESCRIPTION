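Package: tumorlat
Title: On-Lattice Stochastic Simulation of Tumor Growth and Intratumor
    Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven, single-node on-lattice simulator of tumor growth
    from a single cell. Cell division waiting times follow a gamma
    distribution whose shape parameter interpolates between exponential
    (memoryless) and synchronous (deterministic) division, with explicit
    cell-cycle conditioning for cells that have not divided recently.
    Supports regular and hexagonal lattices in two and three dimensions
    (Moore, von Neumann, and hexagonal/face-centered-cubic neighborhoods),
    density-dependent birth models (constant, step, linear in the fraction
    of empty neighbor sites), four daughter-cell placement ("push") methods,
    cancer stem cell differentiation into transient amplifying and
    terminally differentiated cells, driver mutations multiplying birth,
    death, and migration rates, and an environmental-change schedule.
    The analysis layer computes growth curves, per-cell division counts,
    founder-lineage fractions, and branch-length F_ST between spatial
    subregions as a function of physical distance, together with TSV and
    Newick exports of the cell genealogy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
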