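Package: poretrans
Title: Langevin Dynamics of Forced Polymer Translocation Through a Nanopore
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin-dynamics simulator of driven polymer
    translocation through a narrow cylindrical nanopore with tunable
    monomer-pore attraction. A bead-spring chain (FENE bonds, WCA excluded
    volume) is pulled through a finite pore pierced in a continuous membrane
    by a force acting only on beads inside the pore. The package builds
    threaded initial configurations, equilibrates the cis-side tail, runs
    translocation events with reproducible per-event random streams, and
    computes the full observable suite: per-monomer first-passage (waiting)
    times, cumulative exit-time curves and their crossing points, trajectory
    of the chain centre of mass, trans-side aspect ratio, and the
    gyration-to-hydrodynamic-radius shape factor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
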