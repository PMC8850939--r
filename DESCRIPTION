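Package: gcsfcea
Title: Cost-Effectiveness Modelling of G-CSF Primary Prophylaxis in Breast
    Cancer Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness modelling of pegylated
    versus daily granulocyte colony-stimulating factor (G-CSF) primary
    prophylaxis against chemotherapy-induced febrile neutropenia in women
    with stage II-IV breast cancer. Provides a generic discrete-time Markov
    cohort engine with a microsimulation oracle, a 12-week four-cycle
    chemotherapy model with febrile neutropenia, infection and death events,
    a 35-year post-chemotherapy survival model linking febrile-neutropenia
    history to reduced relative dose intensity and survival, synthetic
    patient-level cohort generation, propensity-score matching with balance
    diagnostics, and one-way deterministic plus probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
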