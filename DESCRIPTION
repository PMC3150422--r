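Package: rirrsim
Title: Agent-Based Simulation of Mitochondria-Driven ROS Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulator of ROS-induced ROS release
    (RIRR) in a two-dimensional cell. Mitochondria, reactive oxygen species
    (superoxide and hydrogen peroxide) and antioxidant enzymes (Mn-SOD,
    CuZn-SOD, glutathione peroxidase) are modeled as discrete agents on a
    pixel grid with random-walk diffusion, probabilistic membrane crossing,
    pixel-co-location enzymatic reactions and a sigmoid ROS-dependent
    electron-leakage rule. Includes generators for regular, irregular,
    low-density, moving and gradient mitochondrial network layouts,
    antioxidant intervention sweeps, polynomial dose-response regression
    with RIRR-threshold estimation, messenger lifetime/reach calculators,
    snapshot rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
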