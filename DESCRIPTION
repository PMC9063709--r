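Package: inflomorph
Title: Image-Based Morphometrics and Yield Analytics for Cannabis Inflorescences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-inflorescence morphometrics from calibrated
    photographs of trimmed cannabis inflorescences spread on a contrasting
    surface: blue-band minimum-error thresholding, area opening and
    connected-component labeling yield individual objects, which are
    measured by moment-based best-fit-ellipse length and width, pixel-count
    size, convex hull area and hull perimeter in absolute (cm) units.
    Downstream analytics aggregate objects into per-plant summaries
    (inflorescence number, total coverage), unify fresh and dry measurement
    states by linear calibration, estimate clonal broad-sense heritability
    and trait correlations across a genotype population, apportion plant
    biomass to individual inflorescences, compute cumulative yield-threshold
    fractions, and predict dry biomass from the mean width of the longest
    inflorescences, with a subsampling-error simulation. A synthetic-scene
    and synthetic-population generator provides ground-truthed test data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, png, tiff, jpeg
Suggests: testthat (>= 3.0.0), optparse, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
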