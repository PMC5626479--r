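Package: bumphole
Title: Fixed-Backbone Multistate Protein Design for Obligate Heterodimer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for negative ("bump-hole") design of protein-protein
    interfaces on a fixed backbone. Enumerates discrete side-chain rotamers at
    interface positions, assembles a pairwise van der Waals energy matrix
    (template constant, rotamer self energies, rotamer-pair energies), finds
    the global minimum-energy packing per sequence by exhaustive search or
    dead-end elimination, scores the three dimeric states of a candidate
    sequence pair (heterodimer and the two homodimers), ranks sequence space
    by the specificity gap, and diagnoses designed homodimer failure as a
    steric clash or a packing void. Ships a synthetic idealized helix-bundle
    generator so the full pipeline runs without external structure downloads.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
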