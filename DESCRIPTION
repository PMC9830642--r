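Package: oefield
Title: Oriented Electric-Field Effects on Reaction Barriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the evaluation of a chemical reaction's susceptibility
    to oriented external electric fields (OEFs). Given local-minimum and
    transition-state structures with consistent atom numbering, the package
    computes the reaction dipole axis (the dipole-moment difference between
    the two stationary points), superposes the structures by least-squares
    rigid motion, reorders atoms so the leading atoms form a stable Z-matrix
    frame, maps the reaction axis into each structure's Z-matrix orientation,
    and ramps an applied field of increasing magnitude along that axis via a
    pluggable energy engine. An analytic harmonic point-charge engine permits
    end-to-end testing; a Gaussian-style input writer and log parser support
    external quantum-chemistry workflows. Results are tabulated as
    field-dependent activation energies, barrier changes, dipoles, geometric
    deviations, and linearity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
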