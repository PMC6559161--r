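Package: bgscale
Title: Scale-Dependent Relationships Between Tree Diversity and
    Elevation Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates how taxonomic alpha, beta and gamma diversity of
    forest inventory plot communities relate to elevation heterogeneity
    (standard deviation of elevation) across spatial grains. Diversity is
    measured as Hill numbers of order one (effective species numbers)
    computed from basal-area abundances; elevation heterogeneity is the
    standard deviation of all raster cells inside circular neighbourhoods
    of increasing radius. Relationships are fitted per spatially separated
    plot subsample with gamma generalized linear models (log link) for
    alpha and gamma diversity and beta regression (logit link) for beta
    diversity, slopes are standardized to response standard deviations per
    metre of elevation SD, and percentile confidence intervals are formed
    by repeating the minimum-distance subsampling many times. A synthetic
    module generates fractal elevation surfaces and niche-assembled plot
    communities with a tunable diversity-heterogeneity effect so the whole
    pipeline is testable without restricted inventory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    geosphere,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'seeds.R'
    'plot-communities.R'
    'subsample.R'
    'diversity.R'
    'elevation-raster.R'
    'geodiversity.R'
    'aggregate.R'
    'bgscale-package.R'
    'models.R'
    'io-plots.R'
    'io-raster.R'
    'synthetic.R'
    'pipeline.R'
    'cli.R'
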