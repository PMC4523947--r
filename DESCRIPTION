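Package: contournet
Title: Hierarchical Competitive-Network Model of Boundary-Contour Coding in
    the Ventral Visual Stream
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-layer hierarchical competitive neural network of
    the primate ventral visual pathway (a VisNet-family architecture): a Gabor
    filter bank models V1 simple cells, and successive layers with sparse
    topological connectivity and graded lateral interaction (competitive or
    self-organizing-map) learn via local Hebbian or temporal-trace plasticity
    with synaptic weight renormalization.  Includes generators for parametric
    polygonal shape stimuli built from concave/straight/convex boundary
    elements, closed curvature stimuli in the style of Pasupathy and Connor,
    and smooth synthetic blob objects; presentation-sequence scheduling for
    translation-invariance training; and an analysis battery covering
    single-cell stimulus information, boundary-element selectivity counting,
    receptive-field backtracing, curvature-by-angular-position tuning
    heatmaps, peak counting, and Gaussian-tuning model correlation.  Tabular
    results are tibbles with broom-style tidiers and ggplot2 plot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
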