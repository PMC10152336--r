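Package: walkcoach
Title: Tailored Walking-Coach Message Engine with Geofenced Prompts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A testable engine for an individually tailored mobile walking
    intervention. Coaching messages are selected by elimination from a
    tagged message library using three tailoring parameters: daily step
    count (three performance strata), proximity to green spaces (a 300 m
    geofence over parks, forests and walking trails), and stated
    preferences for ten behaviour change techniques (BCTs), which weight
    a sampling-without-replacement subset selection. A simulated-clock
    scheduler enforces the delivery windows, daily caps and minimum gaps
    of the intervention design and writes an auditable delivery log.
    Synthetic generators for users, step trajectories, GPS tracks, green
    spaces and message libraries make every rule exercisable at desk
    scale without any device data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
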