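Package: groovePMF
Title: Ion-Permeation Energetics of a Membrane-Protein Groove from
    Umbrella Sampling
Version: 0.1.0
Authors@R:
    person("Maintainer", "groovePMF", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compute the energetics of ion permeation through the
    hydrophilic groove of a membrane protein from umbrella-sampling data:
    window-grid construction and histogram-overlap quality control,
    potential-of-mean-force estimation by the weighted histogram analysis
    method (WHAM) with Monte Carlo bootstrap error bars, per-window
    contact counting and "critical interaction" range annotation, average
    permeation-path and maximal-sphere pore-radius profiling, and
    finite-difference linearized Poisson-Boltzmann electrostatics on a
    membrane-slab dielectric model.  A synthetic-data module generates
    overdamped Langevin trajectories on designed groove potentials with a
    known free-energy surface, so every stage is testable end to end
    without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
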