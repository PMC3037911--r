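Package: loopmapr
Title: Topological Mapping of Nuclear-Matrix-Anchored DNA Loops from
    Nuclease Digestion Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for positional mapping of DNA sequences relative to the
    nuclear matrix (NM) using DNase I digestion of nucleoids. Simulates
    stochastic digestion of NM-anchored supercoiled DNA loop populations,
    segments bulk digestion kinetics into topological zones (distal,
    proximal, very close, embedded), assigns loop sequences to zones from
    PCR presence/absence calls, quantifies zone shifts across cellular
    proliferation states, and discriminates among candidate loop
    replication mechanisms (tracking versus reel-in models). Ships encoded
    call-matrix fixtures for a 162 kbp rat albumin-family region and four
    unrelated genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
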