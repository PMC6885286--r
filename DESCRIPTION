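Package: mitoprobe
Title: Membrane Localization and Peroxidation Kinetics of a
    Mitochondria-Targeted Lipid Peroxidation Probe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to model and analyse the membrane behaviour of a
    TPP-conjugated BODIPY lipid-peroxidation probe in a cardiolipin-rich
    bilayer. Provides a seeded coarse-grained bilayer and trajectory
    generator with tunable dye-cardiolipin lateral affinity, enumeration
    of mono-hydroperoxy cardiolipin species, periodic dihedral energy
    models with relaxed torsion scanning and linear least-squares
    parameter fitting, fragment partial-charge assembly, depth density
    profiles and their overlap, dye-aligned lateral occupancy maps,
    lateral radial distribution functions, GROMOS-style conformational
    clustering, and Beer-Lambert quantification of conjugated-diene
    formation from spectrophotometric time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
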