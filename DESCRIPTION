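Package: bhworkforce
Title: Needs-Based Estimation of Behavioral Health Staffing for Community
    Health Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the behavioral health workforce (licensed mental
    health providers, psychiatrists, other mental health staff, and
    substance abuse providers) needed by federally funded community health
    center grantees.  Insurance-stratified prevalence rates of mild or
    moderate mental illness and of illicit drug or alcohol abuse are
    applied to each grantee's medical patients aged 12 and over to obtain
    target treatment populations; median annual visit rates and median
    annual visit loads per full-time equivalent (FTE) convert those
    populations into visit demand and FTE need; per-grantee shortages are
    floored at zero so over-served grantees do not offset under-served
    ones.  Includes a calibrated generator of synthetic UDS-style grantee
    cohorts, national and state aggregation, expansion-scenario
    projection, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    datasets,
    dplyr,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
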