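Package: zntraj
Title: Zhu-Nakamura Trajectory Surface Hopping on Two-State Model Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-adiabatic molecular dynamics by Zhu-Nakamura trajectory
    surface hopping on pluggable two-state potential-energy surfaces.
    Provides analytic linear-crossing (Landau-Zener) models with known
    solutions, a one-dimensional surrogate of the photoinduced ring-closing
    reaction of a nucleoside-based diarylethene photoswitch calibrated to
    published ab initio energetics, Wigner sampling of harmonic initial
    conditions, velocity-Verlet propagation with stochastic surface hops,
    ensemble statistics (state populations, exponential lifetime fits, hop
    and ring-closing statistics, photocyclization quantum yield), and a
    numerically exact split-operator wavepacket oracle used to validate the
    semiclassical hop probability against quantum dynamics and the classic
    Landau-Zener limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
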