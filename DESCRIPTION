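Package: pcond
Title: Airway Opening Pressure from Constant-Flow Ventilator Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of airway closure and measurement of airway opening
    pressure (AOP) in passively ventilated patients from the airway-pressure
    waveform recorded at a usual constant inspiratory flow, using the
    conductive-pressure method: the pressure at the abrupt early-insufflation
    slope break, referenced to PEEP, is compared with the resistive pressure
    (peak minus plateau) so that an excess larger than 1 cmH2O flags closure
    and yields AOP = PEEP + (Pcond - Pres). Includes the standard low-flow
    (5 L/min) reference method, a mechanistic single-compartment
    lung-ventilator simulator with circuit compliance, bilinear compliance and
    an airway-closure threshold, a synthetic patient-cohort generator,
    diagnostic-performance statistics (sensitivity, specificity, predictive
    values, likelihood ratios, Youden index) and Bland-Altman agreement
    analysis, plus waveform file I/O and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
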