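Package: phasorflim
Title: Spectral Phasor and Fluorescence Lifetime Analysis of Two-Photon Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multidimensional two-photon microscopy of
    tissue: spectral phasor transformation and gating of 16-channel emission
    stacks, biexponential fitting of per-pixel TCSPC photon-count decays with
    amplitude-weighted mean lifetime, RGB spectral encoding, SHG/TPEF and TPEF
    spectral ratio statistics, rule-based classification of tumor regions
    (invasive, near-invasive, non-invasive), and one-way ANOVA with Tukey
    multiple comparisons across fields of view. Includes a synthetic tissue
    phantom generator with Poisson photon noise and known ground truth for
    validating every stage, plus TIFF-with-sidecar I/O and tile stitching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
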