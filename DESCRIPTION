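Package: naupflow
Title: Swimming Kinematics and Hydrodynamics of Nauplius Larvae from
    Landmark Tracks and Micro-PIV Velocity Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for high-speed video studies of
    swimming crustacean nauplii. Reads tpsDIG landmark digitizations and
    gridded micro-particle image velocimetry (PIV) velocity fields, and
    computes appendage-beat kinematics (beat frequency, amplitudes,
    angular speeds, phase relationships, forward:backward displacement
    ratios, Reynolds number), vortex circulation, the spatial attenuation
    power of the induced flow, the hydrodynamic area of influence, flux
    through body-anchored reference lines in both the laboratory and the
    body frame of reference, and Lagrangian particle paths. Includes a
    basic multi-pass cross-correlation PIV engine with larva masking and
    outlier rejection, a synthetic-data generator producing landmark
    series, analytic velocity fields, and particle image sequences with
    known ground truth, and permutational two-sample tests for group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
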