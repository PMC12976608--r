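Package: labsched
Title: Conflict-Free Staggered Scheduling of Laboratory Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans staggered execution of identical, time-sensitive sample
    processing protocols by a single operator. Given an ordered protocol of
    hands-on operations with wait times, finds the minimal conflict-free
    staggering interval by a granularity-stepped search, evaluates manual
    intervals, expands simple time courses, and emits schedules, Gantt
    layouts and reproducible report archives. All scheduling arithmetic is
    exact (integer milliminutes); conflict detection uses exact half-open
    interval intersection. Includes a live execution status engine with an
    injectable clock and a benchmark harness for optimizer scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
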