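Package: camosearch
Title: Synthetic Camouflage Scenes, Stereo Rendering and Visual-Search
    Reaction-Time Analysis
Version: 0.1.0
Authors@R:
    person("Camosearch", "Developers", email = "camosearch@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how disruptive coloration interacts with
    binocular depth information in visual search. Synthesises snake
    textures with and without edge-enhancement camouflage from
    forest-like colour palettes, composes metric leaf-litter scenes with
    a deterministic height-field stacking model, renders calibrated
    stereo image pairs with ground-truth target masks, depth and
    disparity under ambient or directional (cast-shadow) illumination,
    simulates observers producing reaction-time data in a fully
    within-subjects 2x2x2 factorial design, and analyses the results
    with the study's exclusion rules, reciprocal transform,
    repeated-measures ANOVA with generalized eta squared, and
    simple-effects t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
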