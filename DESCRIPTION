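Package: ncaging
Title: Neural Cellular Automata for Studying Aging as Loss of Goal-Directedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evolutionary Neural Cellular Automaton (NCA) platform for
    studying aging in silico as a loss of morphogenetic goal-directedness.
    Distributed recurrent-network cell controllers are evolved with CMA-ES to
    grow a target tissue pattern within a fixed developmental horizon, then
    deployed far beyond it. The package provides the NCA dynamical core with
    clipped, noisy state updates and mean-pooled neighbor perception; four
    lifetime perturbation mechanisms (misdifferentiation noise, competency
    gating, permanent gap-junction closure, and diffusive genetic damage);
    plug-in information-dynamics estimators (active information storage,
    transfer entropy, spatial entropy) with per-cell spatial maps; and
    organ-level rejuvenation interventions with threshold-triggered resets,
    boundary augmentation and refractory periods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
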