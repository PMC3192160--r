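Package: volumass
Title: Volumetric Body Mass, Centre of Mass and Muscle Reconstruction from
    Skeletal Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating body mass, centre of mass and inertial
    properties of extinct vertebrates from skeletal geometry. Cross-section
    hoops placed on skeletal landmarks are lofted into watertight segment
    meshes with zero-density air cavities; exact polyhedral (divergence
    theorem) integration yields mass properties; rule-based minimal, maximal
    and centre-of-mass-extreme variants bracket reconstruction uncertainty.
    Includes reconstruction of the M. caudofemoralis longus from caudal
    vertebral landmarks, extensor muscle mass estimation by the
    segment-minus-bone coefficient method, sigmoidal growth-curve fitting
    with a fixed asymptote, developmental mass extrapolation from cubed
    femoral lengths, and AICc/F-test growth model comparison. A parametric
    skeleton generator with analytic ground truth supports validation
    without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
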