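Package: applebruise
Title: Impact-Energy Mapping and Cell-Death-Zone Analysis for Apple Bruising
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying initial impact bruising in apples from
    array-pressure-sensor recordings and stained tissue-section micrographs.
    Reconstructs per-frame hammer kinematics and the per-sensing-point map of
    absorbed impact energy from 40x40 pressure frame stacks, segments the
    sub-surface cell death zone from the HSV saturation channel of trypan-blue
    stained sections, measures depth and width profiles of the zone, and
    correlates depth profiles against energy profiles across drop heights.
    Includes a seed-deterministic synthetic-data module (Hertzian drop-impact
    simulator and section-image renderer) that provides ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
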