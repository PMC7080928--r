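Package: focidose
Title: Quantitative gamma-H2AX Foci Analysis and Internal Dosimetry for
    Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DNA double-strand-break induction in tissue sections
    after internal irradiation from radiopharmaceuticals. Provides a
    two-channel (DAPI / gamma-H2AX) confocal z-stack data model with TIFF
    input and output, a synthetic ground-truth stack generator emulating
    liver and testis morphologies, DAPI-based nucleus segmentation
    (maximum-intensity projection, Otsu threshold, binary median filter,
    distance-transform watershed, fill holes), plateau-aware 3D foci
    detection with shell background estimation and strict voxel-size
    filtering, per-nucleus count statistics (group summaries, zero-foci
    fractions, histograms, one-way ANOVA with Tukey HSD), and a MIRD-style
    internal dosimetry chain (mono-exponential biokinetics, effective
    half-life, residence time, S-value absorbed dose and dose rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
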