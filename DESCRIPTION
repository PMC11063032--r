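Package: seedhtt
Title: Hydrothermal-Time Modelling of Seed Germination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies seed germination responses to temperature and water
    potential. Computes dish-level germination indices (mean germination
    time and rate, germination energy, germination rate index, germination
    index, Timson index, coefficient of velocity, time to 50% germination,
    seed vigor indices) from cumulative count data, fits thermal-time,
    hydrotime and hydrothermal-time threshold models by repeated probit
    regression (recovering the hydrotime constant, the median and spread of
    the base water potential distribution, cardinal temperatures and the
    supra-optimal shift rate), predicts cumulative germination time courses,
    and simulates dish-level experiments from a population model with a
    normally distributed base water potential so that every estimation stage
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
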