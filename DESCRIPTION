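Package: stenoflow
Title: Hemodynamics of Stenosis Microfluidic Models of Thrombosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational hemodynamics for hump-shaped stenosis microfluidic
    channels used to study shear-dependent platelet aggregation. Builds
    parametric eccentric or concentric micro-contraction geometries, solves the
    steady laminar incompressible flow of Newtonian or Generalized Power-Law
    (shear-thinning) blood on a boundary-fitted grid with a coupled
    streamfunction-vorticity discretization, and maps the hemodynamic
    observables that drive platelet mechanobiology: shear-rate fields, wall
    shear stress, platelet-trajectory streamlines with shear and shear-gradient
    histories, and their peaks. Includes closed-form operating-point
    calculators (flow rate, Reynolds and Womersley numbers) for rectangular
    microchannels, a constitutive-viscosity benchmark, grid-convergence
    verification utilities, and parametric sweep drivers over bulk shear rate,
    stenosis level, contraction angle and fluid medium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
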