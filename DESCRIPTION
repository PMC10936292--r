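Package: metamorphsim
Title: Simulation and Digital Suppression of Metamorphopsia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parametric simulation of metamorphopsia (perceived distortion of
    straight lines caused by macular pathology) as mixtures of truncated
    Gaussian distortion kernels, rasterized to displacement and luminance
    maps and applied to Amsler-grid and pseudo-Latin reading stimuli by
    backward image warping.  Provides gaze-locked dark-spot suppression
    overlays sized relative to the distortion extent, dense and parametric
    corrective (inverse) distortions, a simulated binocular observer that
    scores perceived distortion and legibility on 0-5 categorical scales,
    examiner-style calibration procedures against synthetic participants,
    and a repeated-measures study harness with CSV trial logging and
    chi-square analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
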