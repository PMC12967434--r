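Package: ulnakin
Title: Automated 3-D Analysis of Ulnar-Sided Wrist Kinematics from Dynamic CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify ulnocarpal impaction and distal radioulnar joint
    (DRUJ) stability from segmented wrist-bone surface meshes tracked across
    dynamic (4-D) CT frames. Implements four 3-D parameters: 3-D ulnar variance,
    ulnocarpal proximity to the lunate and triquetrum, the 3-D modified
    radioulnar line method and the 3-D epicentre method, together with automatic
    anatomical landmark detection (mean-curvature classification of the sigmoid
    notch, ulnar styloid removal), rigid iterative-closest-point registration of
    static bones to dynamic frames, per-frame parameter evaluation, angle-binned
    cohort summaries, and a parametric synthetic-wrist generator that provides
    exact analytic ground truth for every landmark and parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse,
    withr
Config/testthat/edition: 3
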