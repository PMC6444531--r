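Package: curvepick
Title: Optimal Time-Point Selection for Follow-Up Time-Course Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects the subset of time points of a high-resolution
    time course that best preserves the shape of the underlying curves in
    lower-resolution follow-up experiments. A non-parametric probability
    density over curves is fitted by elastic registration of the training
    curves with the square-root slope function, a Karcher mean of the
    warping functions, and separate functional principal component
    analyses of phase (x-axis) and amplitude (y-axis) deformations.
    The expected squared L2 reconstruction error of a candidate subset --
    of the curves themselves, of the difference to a control condition, or
    of the variance-normalised difference -- is estimated by Monte Carlo
    and minimised exactly over all subsets of a given size with a
    fixed-edge-count shortest-path dynamic programme.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
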