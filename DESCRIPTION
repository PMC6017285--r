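Package: cyclodyn
Title: Molecular Mechanics and Rigid-Body Dynamics of Cyclodextrin
    Host-Guest Inclusion Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the formation of host-guest inclusion complexes between a
    truncated-cone host (such as beta-cyclodextrin) and a small-molecule guest
    in continuum solvent.  Provides an AMBER-style force field (Lennard-Jones,
    continuum-dielectric electrostatics, a 12-10 hydrogen-bond term, and
    harmonic bond/angle plus cosine torsion intramolecular terms), an
    exhaustive position-by-orientation grid scan yielding the penetration
    potential W(Z), Boltzmann-averaged potential energy surfaces and the
    global-minimum complex configuration, a constant-temperature rigid-body
    molecular dynamics engine using quaternion orientations and a leap-frog
    integrator with separately constrained translational and rotational
    kinetic energies, and trajectory observables: residence times, position
    probability densities, ensemble binding free energies and simulation
    summaries.  Synthetic host and guest generators allow every stage to be
    exercised without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
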