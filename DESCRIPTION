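Package: tuberoot
Title: Statistical 3D Simulation of Potato Tuber-Root Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three-dimensional models of the potato (Solanum tuberosum)
    tuber-root system at harvest from field-measured characterization
    parameters. Parameter databases hold per-variety, per-organ probability
    distributions (normal or piecewise-uniform empirical) fitted from
    measurement tables; plants are assembled as child-sibling trees of organ
    nodes (seed potato, underground stem, seminal roots, creeping roots,
    creeping stems, tubers); curved root axes are generated by iterated
    unit-length growth steps with deflection rotations; organ surfaces are
    exported as triangle meshes (Wavefront OBJ, PLY); and simulated root
    depths are validated against measurements with the relative root mean
    square error and its four-level accuracy scale. A synthetic
    field-measurement generator emulating the statistical structure of
    excavation surveys supports end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
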