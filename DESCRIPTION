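Package: lumiphase
Title: Circadian Phase Analysis of Bioluminescence Reporter Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of circadian bioluminescence recordings from tissue
    explants carrying luciferase clock reporters (e.g. PER2::LUC liver
    slices). Implements running-average detrending, trough/midpoint-peak
    calling, inter-peak period estimation, damped-sine fitting, the
    degree-scale treatment-phase convention (ascending zero crossing =
    0/360 degrees, peak = 90 degrees), phase-shift estimation from
    extrapolated fitted peaks before and after a treatment, harmonic
    phase-response-curve regression, dose-response tables with one-way
    ANOVA and Bonferroni post-tests, and efficiency-corrected relative
    qPCR quantification. A seeded synthetic-trace generator with known
    ground-truth phase shifts (phase-response curve times Hill
    dose-response per peptide) makes every pipeline stage testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
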