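Package: nemascreen
Title: Virtual-Instrument Simulation and Analysis of Automated C. elegans
    FRET Calcium Imaging Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hardware-free analysis stack for automated, plate-scale
    functional imaging of C. elegans sensory neurons. Provides a seeded
    virtual instrument that renders dual-channel (FRET donor/acceptor)
    fluorescence z-stacks and time series with known ground truth; neuron
    detection, head/tail orientation and z-autofocus by zero-normalized
    cross-correlation template matching or edge detection; photobleach-
    corrected FRET-ratio quantification with peak and rising-phase slope
    metrics; and interleaved-control screening statistics with percent-effect
    hit calling, aging trajectories and dose-response analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
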