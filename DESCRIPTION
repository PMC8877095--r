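Package: bowlrecon
Title: Single-View 3D Reconstruction of Round Bowls for Food Volume
    Estimation
Version: 0.1.0
Authors@R:
    person("bowlrecon", "developers", email = "bowlrecon@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the interior surface of a round dining bowl from
    a single top-view photograph of an adhesive paper ruler taped centrally
    across the bowl.  The observed distortions of the ruler width and marker
    spacing encode the bowl shape; a constrained nonlinear least-squares
    problem recovers the viewing-ray lengths, which are turned into a
    symmetrized surface-of-revolution model with diameter, depth, capacity
    and a fill-level/volume table.  The reconstructed bowl is then located
    in later meal images from its elliptical rim projection, and liquid or
    food volume is estimated either by matching the visible surface ellipse
    against projected volume levels or by regressing volume on the food
    area ratio (FAR).  A forward simulator generates parametric bowls,
    projected ruler annotations with pixel noise, and simulated fills with
    exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
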