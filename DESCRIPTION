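Package: scnburst
Title: Burst Firing and Circadian Rhythm Analysis for SCN Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal recordings of the suprachiasmatic
    nucleus (SCN): burst-firing detection and bin-ratio statistics on
    multi-electrode spike trains, pairwise synchrony matrices, chi-square
    (Sokolove-Bushell) periodograms, cosinor and Rayleigh circular statistics
    for bioluminescence reporter rhythms, pixel-level acrophase mapping of
    image stacks, calcium-transient detection with burst coincidence, and
    behavioral actogram metrics (activity onsets, cycle-to-cycle variability,
    free-running period). Includes a synthetic-data generator that emulates
    wild-type and GABA-deficient SCN recordings so the full pipeline can be
    exercised and validated without raw data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
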