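Package: markovchannel
Title: Systematic Identification of Ion Channel Markov Model Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven identification of discrete-state Markov
    models of ion channel gating. Enumerates all unique rooted channel
    topologies up to a given number of states (deduplicated by root-preserving
    graph isomorphism, with biophysically motivated limits on state degree and
    cycle length), equips each topology with voltage-dependent transition
    rates that satisfy microscopic reversibility by construction, simulates
    the standard voltage-clamp protocol battery (steady-state activation and
    inactivation, recovery from inactivation, use-dependent block, current
    traces, decay time constants), and fits rate parameters to summary
    voltage-clamp data by multistart adaptive-temperature simulated annealing
    with an SEM deadzone cost, a solution-stiffness penalty, and
    early-stopping overfitting control. Includes synthetic ground-truth
    generators for end-to-end testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
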