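Package: netpls
Title: Net Predictive Association Patterns by Latent-Variable Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis for multicollinear data: a general
    latent-variable projection algorithm with pluggable weight criteria (PCA,
    PLS1, target projection, covariate projection), repeated Monte Carlo
    resampling to select the number of predictive PLS components, stepwise
    adjustment of an outcome and explanatory variables for univariate and
    linearly dependent multivariate covariates, orthogonal variance
    partitions, and selectivity fraction/ratio variable-importance profiles
    with Monte Carlo confidence limits. Includes a synthetic cohort generator
    with known ground truth for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), readxl, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
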