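Package: blanketlab
Title: Exact Analysis of Markov-Blanket Structure in Linear Ornstein-Uhlenbeck Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact algebra for linear Ornstein-Uhlenbeck systems carrying an
    (external, sensory, active, internal) coordinate partition: solenoidal
    (Helmholtz) decomposition of the drift, stationary Gaussian densities via
    Lyapunov equations, Gaussian conditionals and marginals, and machine-checked
    verdicts on the Markov-blanket conditions used in the free energy principle
    literature. Includes seeded generators for structured counterexample systems,
    Gaussian variational free-energy and KL-divergence analysis with feasibility
    and unbounded-divergence probes, lifts to generalised coordinates, and
    Euler-Maruyama simulation for empirical cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
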