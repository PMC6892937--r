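Package: quasiburst
Title: Burst Statistics of Noise-Sustained Brain Rhythms in Stochastic
    Wilson-Cowan Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transient oscillation bursts ("quasi-cycles")
    generated by stochastic excitatory-inhibitory spiking networks of
    pyramidal-interneuron gamma (PING) type. Provides exact Gillespie
    simulation of the microscopic two-state network, Euler-Maruyama
    integration of the stochastic Wilson-Cowan rate equations and of their
    linear noise approximation (LNA), and the stochastic-averaging
    envelope-phase reduction whose dynamics are governed by two master
    parameters: the damping rate and an effective envelope noise strength.
    Includes analytic-signal (Hilbert) envelope and phase extraction of
    band-passed local field potentials, threshold-based burst extraction
    with a two-cycle secondary criterion, per-burst peak-frequency
    statistics, the Rayleigh stationary envelope density, and closed-form
    mean-first-passage-time theory of mean burst duration based on the
    exponential integral.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
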