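Package: famefuel
Title: FAME Profiling, Biodiesel Property Prediction and Microalgal
    Cultivation Metrics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parses fatty acid methyl ester (FAME) shorthand nomenclature
    (e.g. "C18:1n9t"), summarizes compositions into saturation-class totals,
    and predicts biodiesel fuel properties (cetane number, saponification and
    iodine values, degree of unsaturation, cold filter plugging point, cloud
    point, higher heating value, density) from empirical composition-based
    correlations, with compliance checks against the EN 14214 and ASTM D6751
    fuel standards.  Also provides microalgal cultivation metrics (dry biomass
    concentration, volumetric and areal productivity, lipid yield),
    per-time-point treatment comparison (one-way ANOVA with Tukey HSD and a
    compact letter display), and seeded generators for logistic OD680 growth
    curves, Dirichlet-perturbed FAME compositions and harvest records so the
    whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
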