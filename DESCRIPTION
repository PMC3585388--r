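Package: retinamorph
Title: Reconstruction of Flattened Retinae into Standard Spherical Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing retinal flat-mounts into a standard
    spherical retinal space.  A marked-up flat-mount outline (with relaxing
    cuts and tears) is stitched, triangulated into a mesh of roughly equal
    triangles, projected onto a rim-curtailed sphere and relaxed by
    minimising a physically inspired elastic deformation energy.  Data
    points, landmarks and counted sampling boxes are mapped into spherical
    coordinates and summarised with intrinsic spherical statistics (Karcher
    mean, von Mises-Fisher kernel density and regression estimates,
    point-exclusion contours).  Reconstructed coordinates can be transformed
    into head-centred visuotopic coordinates given an optic-axis pose, and
    displayed in azimuthal equidistant, orthographic or sinusoidal map
    projections.  A synthetic flat-mount generator with known spherical
    ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    interp,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
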