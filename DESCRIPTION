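Package: craniomech
Title: Comparative Cranial Biomechanics and Craniodental Functionspaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative cranial biomechanics of herbivorous dinosaurs
    and other vertebrates: jaw and craniocervical muscle force estimation from
    reconstructed volumes via the dry-skull method, a small-strain linear-elastic
    finite-element solver on four-node tetrahedra with node-set loads,
    distributed-coupling constraints, von Mises stress summaries and bite-force
    extraction, paired "ecological" and "structural" (load-per-surface-area
    standardised) biting comparisons, a craniodental biomechanical functionspace
    built by principal coordinate analysis of mixed continuous/binary character
    matrices with missing data, permutational MANOVA of group separation, and
    phylomorphospace projection over occurrence-time-scaled phylogenies.
    Includes seeded synthetic generators for proxy skull meshes, two-grade
    character matrices and Brownian-motion tree data so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
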