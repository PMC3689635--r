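Package: chromoscore
Title: Quantitative Staining-Quality Scores for Chromoendoscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how well a topical dye enhances gastric mucosa
    visibility in chromoendoscopy images. Implements a lesion-to-background
    contrast score (difference of mean gray values between an annotated
    lesion region and a healthy region) and a global texture-variance score
    built on circularly sampled local-binary-pattern neighborhoods, averaged
    over several sampling radii. A synthetic stained-mucosa image generator
    with a planted concentration-dependent appearance model and a
    concentration-series pipeline (aggregation, peak finding, percent
    increase over unstained tissue) allow the full dye-concentration
    optimization workflow to be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
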