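Package: cryodiff
Title: Weighted Difference Maps and Half-Map Statistics for Cryo-EM
    Single-Particle Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical map calculation for cryo-EM single-particle
    analysis. From two unsharpened, unweighted half maps and an atomic
    model, estimates per-resolution-bin noise and signal variances,
    maximum-likelihood D and sigma scale factors, and computes weighted,
    sharpened Fo-Fc difference maps and normalized expected maps. Includes
    electron structure factors via the Mott-Bethe formula with shifted
    hydrogen nuclei, point-group symmetry handling with special-position
    detection, model-based masking with masked-variance normalization, and
    difference-density peak detection for hydrogen analysis. A synthetic
    half-map generator with ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
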