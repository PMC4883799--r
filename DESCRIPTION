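Package: ibdgeo
Title: Spatial and Temporal Population Structure from IBD Segments and
    Ancestry Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying recent demography in admixed, geographically
    structured populations from identity-by-descent (IBD) segments and local
    ancestry tracts. Implements hotspot filtering of IBD calls, pairwise and
    regional relatedness summaries, a census-based coalescent relatedness
    metric with an element-permutation Mantel test, an analytical
    diffusion-coalescent isolation-by-distance model for IBD sharing
    (closed form and numeric oracle, with a finite-genome correction and
    TMRCA posteriors), a discrete-pulse admixture tract-length dating engine
    with model selection, bootstrap confidence intervals, generation-time
    calibration and a sex-biased contribution solver, plus seeded synthetic
    generators (including a forward Wright-Fisher admixture simulator) so
    that every stage runs without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
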