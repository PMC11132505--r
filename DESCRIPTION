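Package: lcdscope
Title: Proteome-Wide Survey of Low-Complexity Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and classifies low-complexity domains (LCDs) in
    protein sequences by sliding-window amino-acid composition and linear
    dispersion, for 20 primary and 380 secondary compositional classes.
    Provides organism-, protein- and residue-level LCD statistics,
    scrambled-proteome enrichment tests (Fisher's exact test with
    Holm-Sidak correction and log odds ratios), per-class GO-term
    enrichment with cross-organism sharing summaries, whole-proteome
    occupancy signatures with Manhattan-distance comparison and
    complete-linkage clustering, and a synthetic-data generator that
    plants LCDs and class-function associations for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
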