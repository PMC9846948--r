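Package: crysmorph
Title: Attachment-Energy Crystal Habit Prediction and Crystal-Solvent
    Interface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting and analysing the morphology of molecular
    crystals grown from mixed solvents, built around the attachment-energy
    habit model. Provides unit-cell geometry (volumes, d-spacings, plane
    normals, crystallographic densities), Laue-class form expansion and a
    Wulff (halfspace-intersection) habit construction with facet-area
    fractions and side ratios, a 12-6 Lennard-Jones plus Coulomb non-bonded
    evaluator implementing the attachment-energy algebra and the
    crystal-solvent interaction-energy decomposition, builders for layered
    crystal/organic/water/vacuum interface models with solvent-accessible
    area ratios, mass density profiles along the surface normal with peak
    and overlap diagnostics, side-ratio regression and solvent-property
    correlation statistics, and seeded synthetic-data generators with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
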