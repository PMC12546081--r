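Package: tortuflow
Title: Extracranial Arterial Tortuosity, Cerebral Blood Flow, and White
    Matter Lesion Burden Analysis
Version: 0.1.0
Authors@R:
    person("Tortuflow", "Developers", email = "tortuflow@example.org",
           role = c("aut", "cre"))
Description: A quantitative neurovascular imaging pipeline linking the
    geometry of the extracranial brain-feeding arteries to cerebral blood
    flow and white matter hyperintensity burden. Provides seeded synthetic
    phantom generators with analytic ground truth (tubular TOF-MRA-like
    volumes, phase-contrast slice pairs, arterial spin labeling volumes,
    lesion/ventricle scenes, cohort tables), threshold-based vessel
    segmentation with 18-connectivity labeling, centerline extraction by a
    second-order fast marching Eikonal solver with sub-voxel geodesic
    backtracking, inflection-count tortuosity metrics (ICM, ICM index, ICA
    angle), phase-contrast flow quantification and parenchyma-normalized
    global CBF, consensus single-delay pcASL CBF quantification,
    periventricular versus deep white matter lesion classification by the
    13 mm distance rule, and a normality-gated cohort statistics layer
    (group comparisons, chi-square, Benjamini-Hochberg FDR, partial
    correlation, multiple linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
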