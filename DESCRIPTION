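Package: cardioem
Title: Multiscale Cardiac Electromechanics of Inward-Rectifier Gain-of-Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation pipeline for the electromechanical consequences of
    Kir2.1 (KCNJ2) gain-of-function, the substrate of short-QT syndrome
    type 3. Couples a human ventricular myocyte model with three
    inward-rectifier current formulations (wild type, heterozygous E299V,
    pure E299V) to pacing and restitution protocols, monodomain tissue
    conduction on desk-scale cables, rings and sheets with reentry
    induction, calcium-driven cross-bridge mechanics with ATP turnover, and
    a closed-loop lumped circulation yielding pressure-volume loop metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
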