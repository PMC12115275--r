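Package: sedem
Title: SeDeM Expert-System Preformulation Analysis for Direct Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SeDeM diagram expert system used in Quality by
    Design preformulation of direct-compression tablets. Computes the twelve
    SeDeM parameters from raw powder characterization measurements (bulk and
    tapped density, Carr index, Hausner ratio, interparticle porosity, cohesion
    index, angle of repose, powder flow time, loss on drying, hygroscopicity,
    fines fraction and particle-size homogeneity index), transforms them to
    standardized radius values on the 12-axis SeDeM diagram, aggregates the
    five incidence factors, and derives the parametric profile index and Good
    Compression Index. Supports corrective-excipient dosing for deficient
    APIs across a sweep of target compressibility radii, full composition
    building with a standardized lubricant mixture, and tablet batch
    evaluation against QTPP/CQA rules (weight variation, hardness, friability,
    disintegration). Includes a synthetic measurement generator with known
    ground truth for validation, reference characterization fixtures, and an
    end-to-end reporting pipeline with SVG diagram export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
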