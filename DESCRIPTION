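Package: glandvolatiles
Title: Heritable Variation Screening of Insect Gland Volatile Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for gas-chromatography peak-area tables from
    isofemale insect lines: reading and batch-normalising aligned peak tables,
    classifying peaks by abundance, sex specificity and retention-time range,
    calibrating retention times to Kovats retention indices with a piecewise
    model and imputing indices for unidentified peaks, matching peaks across
    GC-FID and GC-MS platforms by index tolerance and adjacency with
    sex/mating-category compatibility rating, screening peaks for heritable
    line variation with rank-normal transformation, one-way F tests,
    false-discovery-rate control, marginal means and compact letter displays,
    and multivariate locality analysis via PERMANOVA and PCA-reduced linear
    discriminant analysis. Includes a synthetic study generator with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    MASS,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
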