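Package: cardiosim
Title: Desk-Scale Cardiac Electro-Mechano-Fluidic Simulation and In-Silico Trial Sizing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale multiphysics toolkit for cardiac modelling: ionic
    membrane models with Nash-Panfilov active tension, finite-volume
    monodomain/bidomain electrophysiology on synthetic meshes with
    orthotropic fiber conductivities and a hierarchical conduction-system
    graph, a Fung-law spring-network structural solver, an incompressible
    staggered-grid fluid solver with moving-least-squares immersed-boundary
    forcing and three-element Windkessel outlets, synthetic surface ECG via
    the infinite-medium lead-field integral, loose and strong
    fluid-structure-electrophysiology coupling, and cohort-sizing
    calculators for in-silico clinical trials.  Includes synthetic geometry
    generators (cables, sheets, slabs, an idealized ventricle, a membrane in
    a channel), built-in parameter registries for conductivities, Fung
    elastic constants and Windkessel parameters, and legacy-VTK/CSV/JSON
    input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
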