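Package: eyemech
Title: Ocular Tissue Biomechanics: Hyperelastic-Viscoelastic Models and
    Pressurized Eye Simulation
Version: 0.1.0
Authors@R:
    person("Eyemech", "Developers", email = "eyemech@example.org",
           role = c("aut", "cre"))
Description: Tools for continuum biomechanics of the eye wall under
    elevated intraocular pressure. Implements a combined Ogden
    hyperelastic and Christensen viscoelastic constitutive law for
    incompressible soft tissue, closed-form simulation of uniaxial strip
    tension experiments at prescribed crosshead rates, inverse material
    identification from multi-rate force-displacement curves by NSGA-II
    multi-objective optimization with Sobol design-of-experiments
    initialization, a parametric heterogeneous-thickness eyeball shell
    mesh with labelled cornea, sclera and lamina cribrosa regions, a
    quasi-static membrane solver (dynamic relaxation with follower
    pressure) reporting equivalent stress and strain fields per region,
    and generators for study-like synthetic datasets including lamina
    cribrosa morphometry tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
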