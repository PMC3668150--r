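Package: prrsim
Title: Stochastic Modelling of PCNA Ubiquitylation in Budding-Yeast Post
    Replication Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic stochastic model of the Post Replication Repair (PRR)
    pathway in Saccharomyces cerevisiae, centred on the mono-, di- and
    tri-ubiquitylation of the sliding clamp PCNA after UV irradiation. Provides
    the canonical 23-species/25-reaction mass-action network with nuclear copy
    numbers, a UV-dose to DNA-lesion linear calibration with chi-squared
    cross-dataset model selection, exact Gillespie SSA and tau-leaping
    simulation engines with ensemble statistics, western-blot style isoform
    observables (units and normalized representations), one-at-a-time parameter
    sweeps, Morris elementary-effects sensitivity screening, and a synthetic
    densitometry generator for end-to-end pipeline tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    stats,
    generics,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
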