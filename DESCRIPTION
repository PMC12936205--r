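Package: synaptrack
Title: Microcluster Tracking and Actin Flow Analysis for Immunological
    Synapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel time-lapse fluorescence
    movies of T-cell immunological synapses. Detects T-cell receptor (TCR)
    microclusters, links them into trajectories with velocity-predictive
    tracking, classifies anterograde versus retrograde motion relative to
    the synapse centre, quantifies cortical actin flow by particle image
    velocimetry, segments outward-propagating actin wavefronts by Sobel
    edge detection, scores TCR-wavefront colocalization, and implements a
    phenomenological tracer model of TCR transport coupled either to
    wavefronts or to the measured flow field. A synthetic movie generator
    with full ground truth makes every stage testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
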