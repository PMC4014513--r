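Package: songsim
Title: Automated Similarity Scoring of Birdsong Imitation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a pupil songbird imitates a tutor song
    without segmenting the pupil's vocalizations into syllables. Songs are
    represented by multitaper spectral features sampled every millisecond
    (Wiener entropy, frequency modulation, cepstral pitch and pitch
    goodness, spectral gravity center and width), distances between tutor
    and pupil frames are calibrated against an empirical null built from
    unrelated songs, and tutor syllables are greedily matched onto the
    continuous pupil stream to yield acoustic, sequence, and composite
    similarity-index (SI) scores. Includes automated pupil-segment
    selection, self-/cross-similarity contrast experiments, feature-subset
    sweeps, and a synthetic zebra-finch-like song generator so the whole
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
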