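Package: nfkbosc
Title: Bifurcation and Sensitivity Survey of an NF-kB Signalling Oscillator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical continuation tools for a deterministic two-feedback
    NF-kB/IkBa/A20 signalling model under TNFa stimulation. Locates
    equilibria of the reduced 11-variable system, classifies their linear
    stability, continues equilibrium branches in the stimulation intensity
    and in any second model parameter, detects and refines Hopf bifurcation
    points, extracts limit-cycle periods and envelopes by stiff integration,
    and computes slope-based sensitivity scores for the Hopf location and
    the oscillation period. Includes analytically solvable oscillator
    fixtures (Hopf normal form, Brusselator) for validating the numerical
    machinery.
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
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
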