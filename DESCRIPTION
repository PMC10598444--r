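Package: boolmod
Title: Modular Decomposition and Dynamics of Synchronous Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural and dynamic decomposition of
    synchronous Boolean network models of gene regulation. Networks are
    decomposed into modules (strongly connected components of the wiring
    diagram) connected by an acyclic graph; module attractors are composed
    into whole-network attractors through semi-direct products and
    non-autonomous (periodically forced) dynamics. Includes exhaustive and
    sampled attractor identification, phenotypical robustness and Derrida
    values, composition of module-level node and edge controls, a generator
    of random modular nested-canalizing networks with fixed in-degree, and a
    simulation pipeline relating modularity to dynamical complexity and
    robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
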