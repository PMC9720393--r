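Package: seedbankr
Title: Soil Weed Seed Bank Community Analysis for Organic Rice Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing soil weed seed bank surveys from organic rice
    production systems: seed-count to density conversion, phytosociological
    parameters (frequency, density, abundance and importance value),
    quadrat-level diversity indices (Shannon, Simpson, evenness, ecological
    dominance), Bray-Curtis dissimilarity with non-metric multidimensional
    scaling and permutational multivariate analysis of variance implemented
    from first principles, boosted regression tree attribution of farming
    practice influence on guild composition, and consecutive planting year
    trend analysis with LSD post-hoc letters. Includes a calibrated synthetic
    survey generator emulating a multi-site quadrat design so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rpart,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
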