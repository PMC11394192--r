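Package: osmofreeze
Title: Response-Surface Optimization of Osmotic Dehydration and
    Shelf-Life Kinetics of Frozen Produce
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for osmodehydrofreezing process analysis: mass-transfer
    and quality indices of osmotic dehydration (water loss, solid gain,
    CIELab colour change, drip loss), three-factor Box-Behnken designs with
    second-order response-surface fitting and ANOVA diagnostics,
    multi-response optimization via Derringer desirability functions, and
    Arrhenius-based degradation kinetics of frozen storage (zero- and
    first-order quality loss, shelf-life computation, effective temperature
    of fluctuating profiles, non-isothermal prediction and validation).
    Includes synthetic-data generators emulating a cherry-tomato
    osmodehydrofreezing study and a reproducible end-to-end report driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
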