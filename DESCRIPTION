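Package: presee
Title: Parameter-Free MDL-Based Segmentation of Time-Series Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Online piecewise-linear segmentation of time-series streams by
    minimum description length (MDL/MML) model selection. A sliding-window
    greedy scan emits "character points" whose connecting segments
    approximate the stream, trading the code length of the hypothesis
    (segment lengths) against the code length of the data given the
    hypothesis (perpendicular and angle distances of the original lines to
    each candidate segment). Includes a bottom-up benchmark segmenter, a
    bounded mean-reverting random-walk stream generator, segmentation
    error-rate and compression statistics, plain-text stream readers and
    writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
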