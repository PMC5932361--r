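Package: i3gauxin
Title: Dynamics of Indole Glucosinolate Hydrolysis and Auxin Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator for the incoherent feedforward loop that couples
    indole glucosinolate (I3G) hydrolysis to auxin signaling in Arabidopsis
    thaliana. Five coupled ordinary differential equations describe
    myrosinase-catalysed hydrolysis of a constant I3G pool into
    indole-3-acetonitrile (IAN) and isothiocyanate-derived auxin
    antagonists, nitrilase conversion of IAN to indole-3-acetic acid (IAA),
    and competitive binding of IAA and antagonists to the TIR1 auxin
    receptor. The package ships the published kinetic parameter registry
    (myrosinase and nitrilase isoforms, docking-derived dissociation
    constants), integrates the model through mustard-oil-bomb and sustained
    cell-autonomous hydrolysis scenarios with a stiff solver, reduces
    TIR1:IAA trajectories to response metrics (drop, recovery, overshoot),
    and scripts the standard parameter-sweep experiments.
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
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
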