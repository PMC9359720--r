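Package: patox
Title: Photoacoustic Tomography Oximetry and Treatment-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal photoacoustic (multispectral
    optoacoustic) tomography studies of tumor treatment response. Provides
    linear spectral unmixing of multispectral image stacks into oxy- and
    deoxyhemoglobin contributions with region-of-interest oximetry (apparent
    oxygen saturation SO2 and reference-normalized total hemoglobin),
    responder/nonresponder allocation from tumor growth curves on the
    cube-root scale via a slope threshold and a hard expectation-maximization
    algorithm over linear mixed growth models, hierarchical and piecewise
    linear mixed models for longitudinal biomarkers with a slope change at a
    configurable knot, Monte Carlo power analysis for clustered two-group
    designs, endpoint statistics (variance-aware t tests, Pearson
    correlations, log-rank tests), and a synthetic-data module that generates
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    nlme,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'patox-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synth-growth.R'
    'classify.R'
    'em.R'
    'evaluate.R'
    'extinction.R'
    'stats.R'
    'longmodel.R'
    'synth-survival.R'
    'synth-oximetry.R'
    'io.R'
    'synth-phantom.R'
    'unmix.R'
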