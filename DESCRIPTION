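Package: vnstrigger
Title: Closed-Loop Trigger Algorithms for Movement-Paired Vagus Nerve
    Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for closed-loop vagus nerve stimulation
    (VNS) triggering during motor rehabilitation. Converts raw movement
    sensor streams (rotation angle, force, touch-swipe speed) into
    smoothed rate-of-change signals, implements three stimulation trigger
    policies -- a dynamic rolling-percentile threshold, a static multiple
    of a calibrated noise floor, and a fixed periodic timer -- and
    computes the selectivity, triggering-rate and inter-stimulus-interval
    metrics used to compare them. Includes a seeded generator of
    synthetic bursty rehabilitation sessions and a simulated therapist
    observer so triggering studies can be run without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
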