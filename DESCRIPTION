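Package: cancelr
Title: Administration-Free Analysis of Cancellation (Multitarget Visual Search) Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates Landolt-C style cancellation task layouts, processes raw
    click/touch event logs into cancellation sequences, and computes the full
    roster of quantitative cancellation measures used in neuropsychological
    assessment of hemispatial neglect and search organization: omissions (total
    and per half), immediate and delayed revisits, horizontal and vertical
    center of cancellation, mean and standardized inter-cancellation distance,
    inter-cancellation timing, search speed, Q score, path self-intersection
    count and rate, best R, standardized inter-cancellation angle, and first
    marking. Includes a synthetic-participant simulator with controllable
    search strategy, lateralized omission gradients, revisiting and timing;
    Gaussian-kernel cancellation/omission/intersection heatmaps normalized to
    optimal performance; cancellation-path and best-R plots; single-page A4 PDF
    reports; batch scoring; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
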