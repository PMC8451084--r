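Package: cvgrn
Title: Gene Regulatory Network Inference with Complex-Valued Ordinary
    Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory networks from
    gene-expression time series using complex-valued ordinary differential
    equation (CVODE) models dZ/dt = sum_k beta_k e_k(Z) with complex
    coefficients beta_k.  Model structures are evolved by grammar-guided
    genetic programming over a context-free expression grammar, complex
    coefficients are fitted with a complex-valued firefly algorithm, and a
    gene's regulators are read off as the variables appearing in its optimal
    model.  Includes min-max normalisation and real/complex conversion modes,
    decoupled Runge-Kutta integration of per-gene models, network accuracy
    metrics (sensitivity, specificity, prediction RMSE), and a synthetic
    benchmark generator with known ground-truth networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
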