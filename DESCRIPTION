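Package: venonet
Title: Lumped-Parameter Modelling of Cerebrospinal Venous Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An anatomy-based lumped-parameter (resistive network) simulator of
    the cerebrospinal venous system. Each vein is a Poiseuille resistance; the
    steady-state nodal system implied by mass conservation is assembled as a
    sparse conductance matrix and solved directly, giving node pressures and
    signed per-vessel flow rates. Includes a bundled synthetic reconstruction
    of the cerebrospinal venous anatomy, morphological interventions (stenosis,
    occlusion, collateral insertion, diameter overrides), parametric occlusion
    sweeps, reflux detection, threshold analysis, Reynolds numbers, and an
    exact one-sample Wilcoxon signed-rank comparison of model estimates
    against measured flows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
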