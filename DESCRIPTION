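Package: invasionquant
Title: Quantification of Glioblastoma Invasion into Brain Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of glioblastoma invasion into
    brain organoids from fluorescence confrontation assays. Delineates the
    merged organoid cluster by seeded region growing, decomposes its outline
    into brain and tumor ellipses fitted to the two lobes of the contour,
    and computes pixel-based invasion metrics: the competitive invasion
    ratio (brain area replaced by the contiguous tumor mass), the
    single-cell invasion ratio (brain area occupied by tumor components
    detached from the core), and their sum. Also analyses exported
    time-lapse cell trajectories (windowed invasion speed in micrometres per
    hour, boundary-reversal events, post-mitotic daughter-cell divergence)
    and ships a synthetic confrontation-scene and random-walk generator with
    pixel-exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
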