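Package: xylemtrace
Title: Identification of Conductive Xylem Vessels from Paired Bright-Field
    and Epifluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end workflow for quantifying functional (water-conducting)
    xylem vessels in Arabidopsis thaliana inflorescence-stem cross sections.
    Detects vessel lumens in bright-field micrographs, scores secondary-wall
    completeness and the fluorescently stained fraction of each wall perimeter,
    applies the two conductivity criteria (fully developed walls in bright
    field; more than half of the perimeter stained in epifluorescence),
    computes experimental hydraulic conductivity from balance flow traces and
    theoretical Hagen-Poiseuille conductivity from vessel diameters, and
    produces paired bright-field versus epifluorescence comparison reports.
    A seeded synthetic-data module generates ground-truth-annotated vascular
    bundle images and flow traces so every stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
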