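Package: prehear
Title: Analysis of Prehearing Cochlear Activity and Auditory Brainstem Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of spontaneous activity in the developing
    auditory system: gamma-waiting-time burst detection on spike trains of
    auditory brainstem (MNTB) neurons, moving-average-subtraction event
    detection on DIC and Fura-2 ratiometric imaging stacks of Kölliker's
    organ, frequency-response-area tuning metrics (characteristic frequency,
    threshold, Q factors), and glutamate-uncaging input-map quantification of
    MNTB-to-LSO connectivity. Includes seeded synthetic-data generators that
    emulate wildtype and conditional-knockout phenotypes with ground-truth
    labels, group-level statistics, and an end-to-end reproducible pipeline.
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
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
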