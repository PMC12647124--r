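Package: airwayplug
Title: Quantitative Microanalysis of Airway Mucus Plugging in 3-D Lung Volumes
Version: 0.1.0
Authors@R:
    person("airwayplug", "developers", email = "airwayplug@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying intraluminal mucus in 3-D micro-CT style
    volumes of murine airway trees: synthetic tubular phantom generation with
    known ground truth, marker-constrained watershed lumen segmentation with
    skeleton-based branch decomposition, mucus segmentation by banded
    thresholding and morphology, airway cross-section extraction by slice,
    skeleton and geodesic level-set methods, mucus area and contact ratio
    metrics with green-to-red 3-D ratio maps, an 11-generation five-lobe
    monopodial airway nomenclature with ordinal mucus scoring, and the
    accompanying nonparametric statistics (Mann-Whitney U, Bonferroni-Dunn,
    Kruskal-Wallis with Dunn's post-hoc, Pearson correlation, simple linear
    regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
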