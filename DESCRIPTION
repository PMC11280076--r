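Package: oculopk
Title: Ocular Physiologically Based Pharmacokinetics of Topical Ophthalmic Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compartmental ocular pharmacokinetic modelling of topically
    administered ophthalmic suspensions: pre-corneal tear dynamics with
    nasolacrimal drainage, shrinking-sphere particle dissolution, Weibull
    controlled-release depots, tissue-to-tissue permeation, systemic
    disposition, and a nasolacrimal/gastrointestinal absorption depot.
    Includes species physiology registries (rabbit and human) for
    interspecies extrapolation, weighted least-squares parameter fitting
    with seeded multi-start optimisation, synthetic study generation with
    lognormal inter-animal noise, and summary pharmacokinetic metrics
    (Cmax, Tmax, AUC, fold errors). The bundled parameter set reproduces a
    besifloxacin 0.6% w/v suspension case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
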