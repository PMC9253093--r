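Package: conchydro
Title: Hydrostatics and Jet-Propulsion Hydrodynamics of Planispiral Cephalopod Conchs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the biomechanics of externally shelled cephalopods
    (ammonoids and nautiloids). Generates theoretical planispiral conch meshes
    (shell, septa, soft body, cameral volumes, displaced water) on a
    logarithmic-spiral sweep, computes mesh-based hydrostatics (neutral-buoyancy
    chamber fill, centers of buoyancy and mass, stability index, apertural and
    thrust angles), solves biomimetic-robot mass budgets (ballast mass and
    placement, counterweight stabilization, component moments of inertia),
    simulates jet-propelled linear and yaw trials of a rigid body under
    quadratic drag, extracts kinematics from tracked-point trajectories
    (velocities, acceleration fits, rocking, yaw), estimates drag coefficients
    from coasting deceleration, and compares trial groups with Welch ANOVA and
    Games-Howell post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
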