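Package: oncosim
Title: Cell-Level Stochastic Simulation of Tumor Initiation and Immune Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An off-lattice, center-based simulator of the earliest stages of
    tumor formation in a small patch of epithelial tissue. Individual
    epithelial cells, tumor cells and T-cells migrate by haptotaxis,
    chemotaxis, contact repulsion and random walk, grow through an explicit
    G1/S/G2/M cell cycle, divide, mutate, die under pressure, and interact
    with small blood vessels (T-cell extravasation, tumor-cell
    intravasation). Chemokine concentrations and gradients are evaluated
    mesh-free by superposing heat-kernel fundamental solutions over the
    recorded trajectories of live and dead tumor cells; cell-cell repulsion
    uses Hertz contact strain energies; migration follows overdamped
    stochastic differential equations integrated with a Runge-Kutta /
    Euler-Maruyama scheme under a quarter-diameter displacement cap.
    Results are returned as tidy tibbles with broom-style tidy() and
    glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
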