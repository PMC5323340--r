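Package: homolseries
Title: Nontargeted Homologue-Series Extraction from LC-HRMS Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-staged, nontargeted detection of homologue series in picked
    LC-HRMS peak lists. A first stage embeds every peak into a four-dimensional
    space of m/z, two mass-defect coordinates and retention time, and uses a
    k-d tree to enumerate all peak triplets compatible with user-set bounds on
    m/z difference, mass-defect slope and retention-time difference. A second
    stage recursively recombines overlapping triplets into longer series
    tuples, enforcing smooth retention-time trends via cubic smoothing
    splines. Utilities cover blank voting, monoisotopic voting, peak-sharing
    series pairing with intersection angles, cross-sample mass-difference
    prevalence, a synthetic peak-list generator with planted series, and a
    randomization-based false-series rate estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
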