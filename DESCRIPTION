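Package: fingermap
Title: Mapping a C2H2 Zinc-Finger Protein-Interaction Interface from NMR
    Titration Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for NMR chemical-shift-perturbation mapping
    of protein-peptide interfaces, built around the CLAMP zinc-finger /
    MSL2 interaction in the Drosophila dosage compensation system. Computes
    combined amide chemical-shift perturbations from HSQC titration series,
    fits a global dissociation constant under the fast-exchange quadratic
    binding isotherm with residue-level bootstrap confidence intervals,
    calls interface hotspot residues, numbers C2H2 zinc-finger residues
    relative to the recognition helix and scores their typicality against a
    position-probability profile, and estimates backbone order from
    secondary chemical shifts via a random-coil-index style parameter. A
    seeded synthetic-data generator produces titration series, alignments
    and shift tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
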