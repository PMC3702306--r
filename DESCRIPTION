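Package: phosloc
Title: Phosphosite Localization from ETD Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping phosphorylation sites on proteins from
    electron transfer dissociation (ETD) tandem mass spectra: in-silico
    tryptic digestion with missed cleavages, theoretical c/z-dot fragment
    ladders with the pre-proline suppression rule, tolerance-based peak
    matching against MGF peak lists, and phosphate localization by the
    bracket-gap mass-difference method using site-determining ions. A
    seeded synthetic-spectrum generator with peak dropout, m/z jitter and
    noise peaks makes the whole pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
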