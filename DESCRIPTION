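Package: h2sindex
Title: Peak-Sensitive Hydrogen Sulfide Exposure Characterization from
    Personal Gas-Detector Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing occupational hydrogen sulfide (H2S)
    exposure from time-stamped personal electrochemical gas-detector logs
    and worker logbooks. Parses detector CSV exports, detects excursions
    above the detection floor, computes band-wise peak counts and
    durations, the daily H2S exposure index, 8-h time-weighted averages
    and ceiling-value exceedance; cleans and encodes logbook activity
    metadata; aggregates readings to one record per worker-day with
    imputation of left-censored (below-LOD) days; summarizes study
    datasets collected under expert-campaign, routine self-assessed and
    intensive self-assessed sampling strategies; fits variance-components
    mixed models (between- vs within-worker) with split-half robustness
    checks; and simulates synthetic worker cohorts with sporadic
    log-normal exposure peaks so every pipeline stage is testable without
    access to the original measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
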