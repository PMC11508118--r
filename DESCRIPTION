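Package: inundr
Title: DEM-Derived Inundation Scoring and Field-Trial Statistics for
    Rainfed Lowland Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Terrain analysis and biostatistics for phosphorus management
    trials in rainfed lowland rice. Implements a DEM-based inundation score
    (focal smoothing, depression filling, D8 flow accumulation, logarithmic
    transform, longitudinal and cross-sectional convexity, and a zero-clipped
    composite score), packaged site, trial and soil-horizon tables from a
    seven-field survey on the Central Plateau of Burkina Faso, seeded
    generators for synthetic DEMs and trials, and the statistical layer that
    relates the score to soil texture, water regime and grain yield
    (simple regression with adjusted R-squared, rank and product-moment
    correlation, Welch t-tests, one-way ANOVA with Tukey HSD letters,
    standardized PCA, and base-saturation indices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
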