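Package: neurofield
Title: Interface Dynamics for Amari Neural Fields on Bounded Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Amari-type neural field equations with a Heaviside
    firing rate on bounded one- and two-dimensional domains with Dirichlet
    boundary conditions. Implements the interface (contour) reduction of the
    field dynamics: normal-velocity rules built from line integrals of a ring
    potential, steady bump and spot construction on intervals, rectangles and
    discs, Evans-function linear stability of localised states (including
    azimuthal spot modes), and full space-time reference simulators for the
    classical model and its gradient reformulation, used to cross-validate
    the interface engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
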