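Package: skindose
Title: Skin (Surface) Dose Estimation for Radiotherapy Treatment Fields
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A general dosimetry system for estimating the skin (surface)
    dose delivered by external-beam radiotherapy, intended for dose
    reconstruction in epidemiologic studies of second cancers and other
    late effects. Given a beam class (megavoltage or cobalt-60), the
    equivalent-square field size, the presence of a block tray, and the
    position of a surface point relative to the field (in-field, under a
    shielding block, near the field edge, far out-of-field, or on a
    tangential surface; entrance or exit side), the package computes skin
    dose as a percent of the Dmax dose and as absolute dose per treatment
    plan. Includes percent-depth-dose table interpolation, an out-of-field
    dose-at-depth model, plan-level dispatch and summation over beams, a
    validation harness against anthropomorphic-phantom measurement
    scenarios, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
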