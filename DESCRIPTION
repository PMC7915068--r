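Package: hallgait
Title: Gait Monitoring with a Wearable Hall-Effect Sensor and Ring Magnet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for a leg-worn gait monitor built from a
    linear ratiometric Hall-effect sensor facing an axially magnetized ring
    magnet on the opposite leg. Converts timestamped 10-bit ADC traces into
    per-stride leg-gap widths (a proxy for stride width) via an on-axis
    ring-magnet field model and its numerical inversion, detects mid-stance
    peaks with a minimum-separation and prominence filter, derives cadence
    from adjacent peak times, and runs a nonparametric statistical battery
    (Lilliefors normality screening, skewness/kurtosis classification,
    1.5-IQR outlier removal, Kruskal-Wallis and Levene comparisons against
    normal gait) to flag abnormal (fast/slow) and irregular (antalgic)
    stride types. Includes a seeded synthetic-trace generator emulating a
    four-subject, five-stride-type cohort so the full pipeline is testable
    without logged hardware data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    nortest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
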