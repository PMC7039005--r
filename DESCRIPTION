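Package: iflinkc
Title: In Silico Iterative Functional Linker Cloning and Protease-Switch Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates iterative functional linker cloning (iFLinkC), a type IIS
    restriction/ligation DNA assembly scheme that fuses functional protein
    domains with peptide linkers through bridging glycine residues. Provides a
    double-stranded DNA model with typed sticky ends (BtsI, BsrDI, EcoRI,
    SpeI), a sequence-verified registry of linker and domain parts with
    forbidden-site validation and codon-policy reverse translation, an engine
    that executes digest-select-ligate assembly cycles and regenerates entry
    plasmids, a combinatorial library planner with occupancy-based coverage
    statistics, and screening analytics for protease-switch kinetics: initial
    rates, fold induction/repression with propagated errors, and hyperbolic or
    tight-binding (Morrison) dose-response fits for KD and Ki. Deterministic
    fixture generators emulate entry/destination backbones, domain stand-ins
    and plate-reader traces so all analyses run offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
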