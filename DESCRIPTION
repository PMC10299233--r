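Package: scaffoldquant
Title: Microstructure, Alignment and Tensile Characterization of Freeze-Cast Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of anisotropic freeze-cast biopolymer
    scaffolds from micrograph images and traction-test logs. Provides pore
    segmentation of transversal SEM cross-sections (thresholding, connected
    component labeling, per-pore geometry and normalized size distributions),
    coherency-weighted structure-tensor orientation analysis of longitudinal
    micro-channel textures, stress-strain feature extraction (viscoelastic
    modulus, maximum tensile strength, elongation at break) from traction logs,
    factorial ANOVA with Tukey-Kramer post hoc comparisons, and seeded
    synthetic-data generators (pore fields, striped channel textures, J-shaped
    stress-strain curves, freezing-ramp temperature logs) with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    nortest,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
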