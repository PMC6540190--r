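Package: canopytherm
Title: Thermography-Based Drought Phenotyping from Paired Visible and Thermal Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening plant genotypes for drought response with canopy
    thermography. Segments canopies in visible images by mean-shift clustering of the
    CIELAB a*/b* channels, aligns the visible and thermal sensors with a least-squares
    projective transform estimated from annotated corresponding points, applies a
    greybody radiometric correction, extracts masked canopy pixel temperatures, and
    summarises drought-induced canopy temperature increase (delta-CT) alongside
    physiological variables (leaf relative water content, Fv/Fm, water-use efficiency,
    gravimetric soil water content). A factorial analysis stage routes Tukey comparisons
    by the treatment-by-genotype interaction and renders compact letter displays, and a
    Pearson correlation report applies standard interpretation bands. A synthetic scene
    generator with full ground truth makes the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
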