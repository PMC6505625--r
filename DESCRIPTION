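Package: geohedon
Title: Mobility and Expressed Happiness in Geolocated Message Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing human mobility and expressed happiness
    from geolocated short-message streams. Computes per-user radius of
    gyration and expected locations on a spherical Earth, normalizes
    trajectories into a common home--work reference frame via the inertia
    tensor, extracts tweet locales (tight non-overlapping visit clusters)
    and their Zipf rank-probability structure, scores texts with a
    lexicon-based hedonometer with a tunable neutral band, decomposes
    happiness differences between texts into ranked per-word contributions
    (word shifts), and measures spatial autocorrelation (Moran's I,
    Geary's C). Includes a seeded synthetic-population generator with
    exposed ground truth so every pipeline stage can be validated by
    parameter recovery without any external corpus.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    ape,
    withr,
    optparse
Config/testthat/edition: 3
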