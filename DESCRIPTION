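Package: pulsegel
Title: Continuous-Flow DNA Fractionation Under Orthogonal Pulsed Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Physical model and simulator for continuous-flow fractionation of
    sub-10-kbp DNA in an agarose-filled chamber driven by orthogonally pulsed
    electric fields of unequal magnitude. Provides field- and length-dependent
    biased-reptation mobility models with derivative access, DNA reorientation
    kinetics, closed-form migration-angle prediction with switching-regime
    classification, a stochastic sawtooth trajectory simulator with
    band-broadening accounting and synthetic fluorescence-image rendering, and
    the downstream measurement chain: image processing, line-profile
    extraction, Gaussian peak fitting, separation resolution, Gaussian-overlap
    purity, and recovery. Includes YAML-configured experiment orchestration
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff,
    minpack.lm,
    EBImage,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
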