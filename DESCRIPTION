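Package: foragevar
Title: Decomposing Forage Nutrient Variation into Species Turnover and
    Intraspecific Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing variation in forage quality (leaf
    contents of N, P, K, Ca, Mg and Na and their stoichiometric ratios)
    across sites along an environmental gradient. Computes specific and
    fixed community-weighted means from layer-abundance vegetation
    surveys and per-site leaf chemistry, partitions across-site variation
    into species-turnover, intraspecific and covariation sums of squares
    with a gradient-explained/residual split, fits site-level regressions
    and within-species mixed models, classifies each element into
    mechanistic hypotheses, and grades nutrient limitation against
    literature-derived herbivore requirement tables. Includes a synthetic
    community generator with known ground truth for every scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
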