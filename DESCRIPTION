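Package: dnaforge
Title: All-Atom B-DNA Models from Smooth Axis Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds all-atom B-DNA models by sweeping idealized base-pair
    templates along a user-supplied smooth helical axis. The axis is a
    piecewise quadratic/cubic Bezier curve (open or closed), sampled at the
    B-DNA rise of 3.4 Angstrom and framed with rotation-minimizing frames
    computed by the double-reflection method, so the strand is torsion-free
    at rest. Local twist is controlled through per-base-pair angular
    constraints interpolated linearly along the strand. Models export to
    fixed-column PDB; simplified representations (axis polyline, helicoidal
    double ribbon, swept tubes for disordered linkers) export to OBJ and
    VRML97. A binary bounding-sphere hierarchy over the base-pair anchors
    supports level-of-detail classification and ray picking. Coarse-grained
    bead trajectories (xyz text or PDB coordinates) can be imported and
    turned into interpolating axis curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
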