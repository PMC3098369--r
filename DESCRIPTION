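Package: gagnmr
Title: NMR-Based 3D Structure Determination of Chondroitin Oligosaccharides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining and analysing solution structures of
    glycosaminoglycan oligosaccharides from NMR data. Implements isolated
    spin-pair NOE intensity-to-distance calibration (I = k * r^-6), flat-bottom
    distance-restraint generation with strong/medium binning, torsion-space
    restrained simulated annealing of 4C1-rigid chondroitin chains, generalized
    Karplus back-calculation of vicinal J-couplings, glycosidic phi/psi torsion
    ensemble statistics with circular means, hydrogen-bond detection, amide
    proton temperature-coefficient analysis, and synthetic-data generators for
    end-to-end validation. Reads and writes multi-model PDB ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
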