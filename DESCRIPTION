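Package: condensaxs
Title: Real-Space Modelling of Biomolecular Condensate SAXS with
    Crosslinking Mass Spectrometry Pipelines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise the interior organisation of
    phase-separated protein droplets from small-angle X-ray scattering
    (SAXS) and chemical crosslinking mass spectrometry (XL-MS).
    Implements reverse-Monte-Carlo fitting of Gaussian-blob and linked
    spherocylinder ensembles to 1-D scattering profiles (Gaussian
    window functions, orientation averaging, clash avoidance, staged
    one- to three-segment refinement), real-space structure metrics
    (radial distribution function in a bounded container, local
    nematic order parameter, mass-fractal dimension, Guinier radius),
    seeded synthetic-data generators for fractal particle arrangements
    and noisy scattering curves, and a post-identification XL-MS
    pipeline (link classification, score filtering, domain mapping,
    transition-area normalisation, differential abundance, and
    condition-specific link selection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
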