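Package: allokin
Title: Allosteric Network Analysis of Motor-Domain Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify allosteric communication in protein molecular
    dynamics trajectories, developed around the kinesin-5 motor domain and its
    catalytic cycle. Implements distance-fluctuation (DF) matrices and their
    state-to-state differences, shortest-path maps built from dynamic
    cross-correlation on a contact-filtered residue graph, a four-step
    loop-conformation clustering protocol with anchored superposition, and
    geometric noncovalent-interaction metrics (pi-stacking, salt bridges,
    hydrogen bonds, radial distribution functions, occupancy densities). A
    synthetic-trajectory generator with known statistical ground truth supports
    validation of every analysis stage without molecular dynamics engines or
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ncdf4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
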