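Package: h2o2sphere
Title: Diffusional Spheres of Influence of Hydrogen Peroxide among Marine Plankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models cell-to-cell diffusional interactions of hydrogen peroxide
    in marine phytoplankton and bacterioplankton communities. Estimates mean
    intercellular spacing from cell suspension density via Poisson
    nearest-neighbour statistics, simulates concentration gradients outward
    from source (phytoplankton) cells and inward toward sink (heterotrophic
    bacterioplankton) cells under volumetric dilution and pseudo-first-order
    decay, solves the threshold radius of each cell's sphere of influence in
    closed form with the Lambert W function, and classifies habitats by
    whether cell-specific spheres of influence overlap mean cell-to-cell
    spacing. Ships a curated table of representative cell sizes and suspension
    densities across oligotrophic, mesotrophic, eutrophic and colonial
    habitats, plus true-scale community visualisations.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
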