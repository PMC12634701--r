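Package: rodspine
Title: Sagittal Spine Instrumentation Biomechanics with Variable-Diameter Rods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates long thoracolumbar posterior instrumented fusion in the
    sagittal plane with an osteo-ligamentous spine model: rigid vertebrae
    coupled by nonlinear functional-spinal-unit joints, elastoplastic
    fiber-section corotational beam rods (constant, stepped and
    Bezier-smoothed variable diameter), pedicle-screw ties, follower-load
    gravity and a staged surgical protocol (prone transition, facetectomies,
    pedicle subtraction osteotomy, rod reduction, standing and flexion).
    Computes the comparative load-transfer metrics used to assess proximal
    junctional kyphosis risk: intervertebral moments, screw forces, rod
    stresses and segmental range of motion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
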