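Package: lnpsaxs
Title: Multi-Shell Sphere and Paracrystal Lamellar Models for LNP SAXS Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and weighted nonlinear least-squares fitting of
    one-dimensional small-angle X-ray scattering (SAXS) profiles of mRNA-loaded
    lipid nanoparticles. Implements a polydisperse core/tri-shell spherical form
    factor combined with a one-dimensional paracrystal lamellar structure
    factor, radial electron-density profiles, a seeded synthetic-profile
    generator that emulates reduced synchrotron data, a parameter-recovery
    harness, and the two small assay formulas (mRNA encapsulation efficiency,
    hemolysis percentage) used alongside such formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
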