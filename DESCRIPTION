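Package: fermkin
Title: Kinetics of Procyanidin Catabolism and SCFA Production in Batch
    Fecal Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of in vitro batch fecal fermentation time courses:
    background (blank-fermenter) correction, least-squares fitting of the
    first-order fractional conversion model C(t) = Cinf + (C0 - Cinf)*exp(-K*t),
    degradation extents, rate tables, pooled standard deviations and two-way
    (donor by matrix) fixed-effects ANOVA. Includes a generative simulator of
    the proposed procyanidin catabolic network (a linear first-order reaction
    system solved exactly) so the full pipeline can be exercised on synthetic
    studies with known parameters, plus composition arithmetic for apple
    matrices (degree of pectin methylation, phenolic class shares).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
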