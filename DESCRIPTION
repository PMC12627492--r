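Package: mocogate
Title: Closed-Loop Simulation of Computer-Vision-Gated, Motion-Compensated MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico testbed for prospective, camera-gated magnetic
    resonance imaging of a behaving insect on a treadmill. A segmented 2D
    digital phantom with semi-periodic abdominal motion is filmed by a
    simulated camera, a markerless Lucas-Kanade optical-flow tracker follows
    a keypoint on the abdomen, and a prospective gating controller releases
    Cartesian RARE k-space shots only when the keypoint is within tolerance
    of a reference pose. Includes a k-space acquisition simulator under the
    inter-scan rigid-motion model, FFT reconstruction, sequence-timing and
    resolution calculators, and quantitative tracking-error and
    image-artifact benchmarks.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
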