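Package: neuromon
Title: Multimodal TCD and Quantitative EEG Brain-Function Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal bedside brain-function
    monitoring in severe acute supratentorial intracerebral hemorrhage.
    Computes quantitative EEG indices (relative delta/theta/alpha/beta band
    powers, delta/alpha ratio, (delta+theta)/(alpha+beta) ratio, and the
    brain symmetry index) from multichannel 10-20 recordings, extracts
    transcranial Doppler waveform indices (systolic, diastolic and mean
    flow velocity, pulsatility index) from velocity envelopes, and runs
    the prognostic analysis: eligibility screening, univariate variable
    selection, backward stepwise logistic regression for 90-day mortality,
    and ROC construction with DeLong comparison of candidate models.
    Includes calibrated synthetic generators for EEG, Doppler envelopes
    and patient cohorts so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
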