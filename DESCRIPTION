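Package: ptmr
Title: Passive Particle-Tracking Microrheology of Fluid Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for passive particle-tracking
    microrheology of colloidal probes at fluid interfaces. Provides
    ground-truth trajectory simulators for the dynamical regimes met at
    bacteria-laden oil-water interfaces (thermal Brownian motion,
    fractional Brownian subdiffusion, persistent random walks, and
    elastic arrest), a renderer that turns trajectories into
    microscopy-like image stacks, a Crocker-Grier style particle
    localizer and trajectory linker, ensemble drift correction,
    mean-squared-displacement estimation, power-law exponent fitting,
    viscoelastic regime classification, and interface-age time-course
    analysis with transition detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
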