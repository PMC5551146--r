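Package: boiledegg
Title: Two-Ellipse Prediction of Intestinal Absorption and Brain
    Permeation from SMILES
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes topological physicochemical descriptors
    (Wildman-Crippen WLogP and molar refractivity, Ertl topological polar
    surface area, atom and bond counts) from SMILES strings, classifies
    compounds for human gastrointestinal absorption and blood-brain-barrier
    permeation by membership in the two BOILED-Egg ellipses in
    (tPSA, WLogP) space, and provides cohort statistics for permeation
    studies: class-level permeant percentages, two-group descriptor
    comparisons with Student's t test, organophosphorus parent/oxon
    metabolite tables, and confrontation of predictions with measured
    fraction-absorbed values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
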