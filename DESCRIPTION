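Package: glitimer
Title: Shh/Gli Incoherent Feed-Forward Loop Timer of Neural Fate Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-node Shh/Gli incoherent feed-forward loop that
    times the switch from motor-neuron to serotonergic-neuron production in
    ventral hindbrain progenitors. Decaying Gli activator and repressor drive
    Tgfb induction and Phox2b repression through weighted Hill functions;
    the package integrates the system deterministically and as a stochastic
    differential equation with multiplicative noise, converts Phox2b levels
    into a differentiation likelihood through a gamma-distributed threshold,
    maps the bistable (hysteretic) Tgfb response by steady-state scanning,
    couples cells on a periodic lattice through Tgfb spatial averaging, and
    reproduces mutant scenarios and noise-robustness sweeps. A companion
    module implements temporal expression-screen filters (down-regulated and
    biphasic gene rules) together with a synthetic expression-table
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
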