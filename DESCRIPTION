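Package: boutonmap
Title: Quantification of Fluorescently Labeled Synaptic Boutons in Brain
    Sections
Version: 0.1.0
Authors@R:
    person("boutonmap", "developers", email = "boutonmap@example.org",
           role = c("aut", "cre"))
Description: Detects presynaptic boutons (~1 micron fluorescent puncta) in
    two-channel 3D confocal stacks, classifies them as reporter-positive by
    regional-maximum colocalization and a bimodal-histogram valley threshold,
    registers sections to a 2D label-map atlas by landmarks, and maps bouton
    counts, densities and reporter-positive fractions per anatomical region
    and on a coarse voxel grid. Links local bouton density to the probability
    of optogenetically evoked inhibitory currents in recorded neurons. A
    seeded synthetic-scene generator with known ground truth drives testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
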