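Package: comodiag
Title: Chemical Saturation and SAR Progression Diagnostics for Analog Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Diagnostics and design tools for medicinal-chemistry analog
    series built around virtual-analog populations. Implements
    neighborhood-based coverage, density, saturation and SAR-progression
    scoring in a configurable physicochemical reference space;
    retrosynthetic fragmentation and series extraction; scaffold-based
    enumeration of diverse and close-in virtual analogs; Free-Wilson
    matched-molecular-pair analysis with local additivity predictions;
    global potency models (Tanimoto-kernel support vector regression and
    ridge regression on extended-connectivity fingerprints) with double
    cross-validation; a recurrent SMILES language model with transfer
    learning onto individual series; and a synthetic-series generator
    with controllable additivity, non-additivity and noise for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    kernlab,
    glmnet,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    tools,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
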