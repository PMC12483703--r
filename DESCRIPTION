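Package: clmda
Title: Cumulative Logistic Multidimensional Data Analysis for Ordinal Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint multidimensional analysis of multiple ordinal response
    variables through cumulative logistic (proportional-odds) models with a
    low-dimensional structural part.  Implements dominance (inner-product)
    models -- cumulative logistic principal component analysis (CLPCA) and
    reduced-rank regression (CLRRR) -- and proximity (distance) models --
    cumulative logistic multidimensional unfolding (CLMDU) and its restricted
    variant (CLRMDU).  Maximum likelihood estimation uses an
    expectation-majorization-minimization (EMM) algorithm whose inner loop is
    ordinary least squares: truncated singular value decomposition for the
    dominance models and a SMACOF unfolding step, extended to negative
    working dissimilarities, for the proximity models.  Includes calibrated
    biplots and triplots, AIC/BIC model selection with indeterminacy-adjusted
    parameter counts, stepwise predictor selection, and a simulation toolkit
    for parameter-recovery and dimension-selection studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
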