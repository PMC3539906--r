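Package: macplan
Title: Restriction-Site Mapping and Modular Assembly Cloning Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps palindromic restriction sites and hybrid ligation sites
    (the non-palindromic hexamers formed by ligating compatible cohesive
    ends from two different restriction endonucleases) on a target DNA
    sequence, models their occurrence statistics in random DNA, partitions
    long fragments into clonable modules bounded by such sites, and
    verifies each partition by in-silico restriction digestion and
    sticky-end ligation. Supports the modular assembly cloning (MAC)
    strategy for seamless, sequence-verified assembly of long DNA
    fragments from individually cloned PCR modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
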