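Package: kinconsist
Title: Thermodynamically Consistent Kinetic Cycle Models
Version: 0.1.0
Authors@R:
    person("Kin", "Consist", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds thermodynamically consistent equilibrium potential graphs
    and nonequilibrium kinetic cycle models from noisy free-energy-difference
    or rate inputs. State free energies are estimated by weighted maximum
    likelihood on the graph with uncertainty propagation through the
    Fisher-information pseudoinverse; inconsistent forward/backward rate pairs
    are projected onto detailed-balance-consistent pairs. Supports
    concentration-, pH- and membrane-voltage-dependent observables (titration
    curves, macrostate free energies), steady-state master-equation solutions
    with transporter turnover numbers, and a zero-temperature Metropolis
    Monte-Carlo inverse approach that infers microscopic parameters (such as
    site pKa values) from macroscopic titration data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
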