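Package: deastrain
Title: Strain-Field Customization for a Dielectric Elastomer Actuator Array
    Bioreactor
Version: 0.1.0
Authors@R:
    person("Strain Field", "Maintainers", email = "maintainers@deastrain.org",
           role = c("aut", "cre"))
Description: Tools for customizing the two-dimensional strain field of a
    bioreactor driven by a 9 x 9 array of independently addressable dielectric
    elastomer actuators (DEAs). Provides a closed-form surrogate simulator of
    the coupled actuator membrane (dual-Gaussian voltage-strain calibration,
    anisotropic inter-pixel coupling, clamped-boundary taper), uniform-strain
    voltage sampling for training-set generation, an image-regression inverse
    controller (target strain image to 81-channel voltage array), a two-stage
    forward controller (voltage array to low-resolution strain image, plus an
    adversarially trained super-resolution stage), structural-similarity (SSIM)
    evaluation with local quality maps, and programmatic demonstration targets
    (concentric annuli, unidirectional gradients, tumour-stroma interfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
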