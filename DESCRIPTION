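Package: dimtrack
Title: Hybrid Manual/Automatic Single-Particle Tracking of Dim Fluorescent Spots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-by-frame single-particle tracking for low signal-to-noise
    fluorescence time-lapse microscopy. Particles annotated in the first frame
    are followed through a small scan region per frame; ambiguous frames (no
    detection, or two overlapping particles) are resolved by a pluggable
    intervention policy that generalizes an interactive prompt to scripted,
    automatic, and ground-truth-oracle decisions. Includes sub-pixel
    localization by intensity centroid or 2D Gaussian fitting, signal-to-noise
    measurement, time-averaged mean squared displacement with closed-form
    relative error bars, diffusion-coefficient and anomalous-exponent
    estimation, kymograph generation, and a synthetic movie simulator with
    ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
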