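Package: grazeclass
Title: Behavior Classification for Grazing Cattle from Collar Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying the behavior of grazing cattle
    (grazing, walking, resting, ruminating, grooming) from collar-mounted
    tri-axial accelerometers. Provides a synthetic collar-signal simulator with
    behavior-specific signatures, ingestion and cleaning of observed-behavior
    records from in-pasture observation and animal-borne collar video, windowed
    feature extraction including ODBA and VeDBA dynamic body acceleration,
    ensemble-tree classification with confusion-matrix performance metrics, and
    experiment drivers for smoothing-window sweeps, structured data-reduction
    bootstraps, observation-source comparison, and nearest-time GPS joining.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    caret,
    jsonlite,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
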