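Package: thermotile
Title: Thermodynamically Screened Whole-Genome Tiling Microarray Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs whole-genome tiling microarray probes by partitioning a
    genome into non-overlapping target fragments and selecting maximally
    specific probes per fragment. Probe specificity is decided
    thermodynamically: every exact-match seed between a candidate probe and
    any nontarget sequence (both strands) is extended into an explicit duplex
    layout and scored with nearest-neighbor enthalpy/entropy models covering
    perfect stacks, single mismatches, bulge loops and dangling ends, so that
    selected probes keep a minimum melting-temperature separation between
    their target and their closest nontarget. Also audits arbitrary probe
    sets for cross-hybridization potential and ships a deterministic
    synthetic-genome generator with planted repeats for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringi,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
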