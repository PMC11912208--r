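Package: revmash
Title: Time-Reversible Integrators for the Mapping Approach to Surface Hopping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic two-state nonadiabatic molecular dynamics with the
    mapping approach to surface hopping (MASH), in which a unit Bloch spin
    vector selects the active adiabatic surface and hops occur when the spin
    crosses the equator. Provides the full family of MASH integrators
    (asymmetric, nonreversible, exactly reversible, and reversible
    piecewise-continuous, the latter locating the hop time by an
    interpolation-based root search), with spin propagation driven by
    nonadiabatic coupling vectors, averaged time-derivative couplings from
    wavefunction overlaps, or local diabatization. Ships analytic avoided
    crossing and linear vibronic coupling models, Wigner and Bloch-hemisphere
    initial-condition samplers, ensemble population observables, and
    convergence-order and reversibility diagnostics. Results are returned as
    tidy tibbles with broom-style tidiers and ggplot2 autoplot methods.
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
    stats,
    utils,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
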