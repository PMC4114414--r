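Package: lifespace
Title: GPS-Based Lifespace Metrics for Mobility Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving life-space mobility measures from timestamped
    smartphone GPS traces. Infers a participant's home location as the modal
    grid cell of recorded coordinates, segments traces into recording sessions,
    detects trips to and from home with a two-state (at-home / not-at-home)
    finite-state machine with a minimum-duration filter, and computes the four
    per-participant Lifespace metrics: furthest distance travelled, mean daily
    distance, percentage of recorded time at home, and trips per week. Includes
    nonparametric group comparison (Mann-Whitney U with tie correction),
    severity-ordered summaries, privacy-preserving mean-subtracted scatter and
    dwell-time heatmap data, and a synthetic GPS trace simulator with ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    geosphere,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
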