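Package: usageviz
Title: Visualization and Analysis of Usage Logs from Web-Based
    Interventions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for exploring engagement with web-based behavioural
    interventions from raw page-view logs. Converts per-participant page
    views into page-group sequences binned into 30-second blocks, renders
    stacked sequence visualizations (individual, frequency, clustered and
    grouped), filters and exports participant cohorts by page-group
    exposure or participant attributes, computes usage and reuse
    summaries, and runs two-group moderator comparisons (pooled and Welch
    t tests, chi-square) between users who did and did not exhibit a
    usage pattern. Includes a synthetic log generator that emulates a
    tunnelled intervention with weekly nonusage attrition and an
    outcome linked to tool reuse, for testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
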