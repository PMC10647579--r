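Package: cavindex
Title: Arterial Stiffness Indexes CAVI and CAVI0: Formulas, Synthetic
    Cohorts and Effect-Modification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the cardio-ankle vascular index (CAVI) and its
    pressure-referenced variant CAVI0 from heart-ankle pulse wave velocity
    and cuff pressures via the Bramwell-Hill relation, converts between the
    two indexes, simulates clinical cohorts with the joint age/blood-pressure
    structure of a geriatric study population (both from fitted regression
    planes and mechanistically through the formula chain), and provides the
    statistical pipeline used to study effect modification of the diastolic
    blood pressure slope by age: stratified group comparison, correlation,
    interaction regression with Freedman-Lane permutation inference,
    prediction surfaces and the crossover age at which CAVI0 becomes
    pressure-independent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
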