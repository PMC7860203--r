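Package: sinusflow
Title: Reduced-Order Modelling of Cerebral Venous Sinus Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reduced-order (lumped-parameter) model of the cerebral venous
    sinus system. Represents the sinus tree from the superior sagittal and
    straight sinuses to the internal jugular veins, computes pressure drops
    from laminar Darcy-Weisbach friction (linear in flow) plus bend and minor
    losses (quadratic in flow), solves the two-inlet/two-outlet network with
    left/right flow splitting, fits the quadratic pressure-flow law, and
    couples venous pressure to intracranial pressure through Davson's
    equation to evaluate whether cerebral hyperemia can induce idiopathic
    intracranial hypertension. Includes cross-sectional vorticity (curl)
    metrics on planar velocity fields, hydraulic and effective diameter
    computation from lumen masks, and a seeded synthetic-data generator that
    emulates patient cohorts and CFD-like pressure and curl outputs for
    testing every pipeline stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
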