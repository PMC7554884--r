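Package: twnring
Title: Topological Water Network Analysis of Binding-Site Hydration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects hydrogen-bonded water rings (topological water networks,
    TWNs) in molecular-dynamics snapshot coordinates. Water pairs are scored
    with the rigid TIP3P pair potential (Coulomb over the nine charge-site
    pairs plus an oxygen-oxygen Lennard-Jones term) and counted as
    hydrogen-bonded below an energy criterion of -2.25 kcal/mol. Chordless
    rings of three to six waters (R3-R6) are enumerated from the resulting
    graph, represented by their centers of mass, assigned to named spherical
    binding-site regions, and summarised as per-region distribution tables.
    The package also provides ultrafast shape recognition (USR) descriptors
    and similarity for comparing TWN point clouds against ligand shapes, a
    Tanimoto-like binding-site similarity score from spatially consistent
    atom matching, a synthetic fixture generator that plants rings in water
    boxes, and a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
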