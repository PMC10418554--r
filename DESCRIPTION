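Package: pulsetree
Title: One-Dimensional Pulse-Wave Hemodynamics of Pulmonary Arterial Networks
Version: 0.1.0
Authors@R:
    person("Pulsetree", "Developers", email = "maintainer@pulsetree.org",
           role = c("aut", "cre"))
Description: Nonlinear one-dimensional blood-flow simulation on bifurcating
    pulmonary arterial trees. Solves the cross-sectionally averaged mass and
    momentum equations with a power-law velocity profile and a linear-elastic
    tube law using a two-step (Richtmyer) Lax-Wendroff scheme, with prescribed
    inlet flow, characteristic-based junction coupling, and three-element
    Windkessel (RCR) outflow boundaries. Provides nominal Windkessel
    construction from catheterization summaries, multi-start nonlinear
    least-squares calibration of global Windkessel scaling factors against
    pressure/area/flow data, wall shear stress physiomarkers (TAWSS, OSI and
    the combined low-shear/high-oscillation fraction), and a synthetic-subject
    generator emulating baseline and chronic thromboembolic pulmonary
    hypertension (CTEPH) hemodynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
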