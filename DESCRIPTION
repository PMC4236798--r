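Package: hedri
Title: Derivation and Application of a Hospital-ED Risk Index for Home-Care Elders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and applying a count-based hospital and
    emergency-department (ED) risk index from dichotomized home-care
    assessment items. Implements the full derivation pipeline: univariate
    odds-ratio screening with risk/protective thresholds confirmed on a
    held-out validation split, a cross-cohort poolability check, staged
    forward stepwise logistic regression (iteratively reweighted least
    squares) with a dual-sample odds-ratio retention rule, and an unweighted
    risk-factor count index with a protective-factor decrement, a six-plus
    cap, and a prior-utilization extension to a 0-12 scale. A synthetic
    multi-cohort generator with a planted logistic outcome model makes every
    stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
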