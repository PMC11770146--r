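Package: depspin
Title: Dielectrophoresis on Inductively Powered Spinning-Disc PCB Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design-and-simulation toolkit for dielectrophoretic (DEP)
    particle manipulation on printed-circuit-board electrodes powered by
    resonant inductive power transfer on a centrifugal (lab-on-a-disc)
    platform.  Models the receiver LC tank (electrode, inter-layer and
    added capacitance; resonance frequency; coupled two-coil frequency
    sweeps with coupling/loss fitting), Clausius-Mossotti spectra and DEP
    forces for homogeneous spherical particles, the electric field of an
    interdigitated electrode unit cell via a finite-difference Laplace
    solve, and overdamped particle trajectories under DEP, Stokes drag and
    the centrifugal body force, classifying trap-versus-wash outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
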