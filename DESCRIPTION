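Package: yeastscape
Title: Quasi-Potential Energy Landscapes for a Budding Yeast Cell-Cycle
    Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs Waddington-type quasi-potential energy landscapes for
    a simplified three-module budding yeast cell-cycle model under intrinsic
    (Gillespie jump-process) and extrinsic (additive white) noise.  Provides
    the deterministic model core (drift, stiff integration, fixed points,
    bifurcation location, parameter sensitivity), the exact 12-channel
    volume-scaled reaction network and its large-deviation Hamiltonian,
    geometric minimum-action computation of local and global
    quasi-potentials with Hamilton-Jacobi diagnostics and the non-gradient
    force decomposition, a local pseudo energy landscape along the
    cell-cycle canal, exact stochastic simulation with finite-volume
    -log(P) landscapes and mean exit times, and named scenario presets for
    nutrient and checkpoint signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    deSolve,
    lhs,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    jsonlite,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
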