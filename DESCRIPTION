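Package: bulkybone
Title: Morphomechanical Simulation of Long-Bone Shaping in Salamander Limb
    Development and Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how rod-shaped skeletal elements acquire their
    shape when tissue growth is driven by oriented cell divisions. The package
    models a long bone as a homogeneous linear-elastic cylinder, discretized
    with structured tetrahedral (P1) finite elements, loaded by region-specific
    internal body-force fields with axial and radial components. Two loading
    configurations contrast normal development (radial growth suppressed in
    the ossifying mid-shaft) with regeneration (uniform growth, delayed
    ossification), reproducing the tapered-versus-bulky shape difference.
    Companion quantification tools include nominal/actual surface-deviation
    maps, axial diameter profiles and a bulge index, labeled-volume bone
    quantification, division-orientation statistics for cell doublets, and
    seeded synthetic-data generators for all inputs. Meshes and results are
    exchanged as VTU/VTK, STL, NRRD/TIFF, CSV and YAML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
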