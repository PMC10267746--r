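Package: sitpress
Title: Seat-Interface Pressure, Contact-Force and Soft-Tissue Metrics for
    Seating Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for validating seated human-body models against
    bench measurements: pressure-mat grid metrics (trial-specific correction
    factor, contact area, peak and mean pressure, sagittal/frontal pressure
    profiles and the four-region seat-pan partition), contact-force frame
    transforms between global and seat-surface-local coordinates with static
    balance checks and Sim-vs-Exp difference statistics, cylinder-ROI
    soft-tissue thickness and volume-reduction metrics on volumetric meshes,
    uniaxial Ogden/neo-Hookean and hysteretic low-density-foam material laws
    with parameter identification, and a seeded synthetic-data generator that
    emulates the measurement chain so the whole pipeline is testable without
    a finite-element solver or a test rig.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tidyr
Config/testthat/edition: 3
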