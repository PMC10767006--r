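Package: arteryMech
Title: Biaxial Extension-Inflation Biomechanics and ECM Fiber
    Microstructure Quantification for Elastic Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of passive arterial wall mechanics from pressure-myograph
    biaxial extension-inflation records (thin-wall mean Cauchy stresses,
    incompressibility-based deformed geometry, in vivo axial stretch detection
    from axial-force invariance, circumferential tangent modulus at mean
    arterial pressure), together with extracellular-matrix microstructure
    quantification from multiphoton z-stacks (FFT-based fiber orientation
    histograms, depth orientation maps, circumferential-to-axial ratios, and
    collagen fiber straightness by distance-transform ridge tracing). Includes
    a four-fiber-family membrane constitutive simulator and a synthetic
    wavy-fiber image renderer providing analytic ground truth for every
    analysis step, plus group statistics (one-way ANOVA with Bonferroni post
    hoc, SEM/SD summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'mechanics.R'
    'simulator.R'
    'imageops.R'
    'orientation.R'
    'straightness.R'
    'synthfibers.R'
    'stats.R'
    'io.R'
    'pipeline.R'
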