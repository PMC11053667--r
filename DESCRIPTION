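Package: dbstdm
Title: Dried Blood Spot Therapeutic Drug Monitoring of Lamotrigine and
    Its Glucuronide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for therapeutic drug monitoring of
    lamotrigine (LTG) and its main metabolite lamotrigine-N2-glucuronide
    (LTG-N2-GLU) from dried blood spot (DBS) samples. Converts whole-blood
    DBS concentrations to plasma equivalents using the haematocrit and a
    blood-cell-to-plasma partition coefficient estimated by nonlinear least
    squares; cross-validates DBS against plasma with weighted Deming
    regression and Bland-Altman agreement analysis; computes the standard
    bioanalytical validation statistics (calibration linearity, LLOQ
    criteria, accuracy/precision, recovery, relative matrix effect via
    calibration-slope RSD, haematocrit and spot-volume effects, stability);
    and screens metabolite-to-parent ratios for metabolic outliers with
    Tukey's fences and a Grubbs test. A seeded synthetic-data generator
    produces every input the pipeline consumes so all stages are testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
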