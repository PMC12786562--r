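Package: crimpsim
Title: Biomechanics of Stapedotomy Prosthesis Crimping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the mechanical coupling between a stapes piston
    prosthesis and the long (lenticular) process of the incus. Provides a
    closed-form open-ring interference-pressure model for self-crimping
    PTFE loops, a parametric quadratic-tetrahedral mesh generator for the
    incus-prosthesis assembly, a small-strain linear-elastic finite-element
    solver with augmented-Lagrangian frictional contact, post-processing of
    von Mises and principal stresses against the 60 MPa cortical-bone
    strength proxy for incudal necrosis risk, and a parameter-sweep /
    Monte-Carlo layer that propagates surgeon crimping-force variability
    into threshold-exceedance probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
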