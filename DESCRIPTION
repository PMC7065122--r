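Package: navmoco
Title: Navigator-Based Detection, Reacquisition and Parallel-Imaging
    Estimation of Motion-Corrupted k-Space for Multi-Echo Spin Echo MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for retrospective correction of brief motion events
    (such as swallowing) in segmented multi-slice multi-echo spin echo
    (MESE) neck imaging.  A ky = 0 navigator echo appended to each echo
    train yields per-slice and per-TR quality scores; after sliding-median
    drift adjustment, a one-sided Hampel rule flags motion-corrupted
    phase-encode lines.  Corrupted central k-space lines are replaced with
    end-of-scan reacquisitions, and remaining corrupted lines are estimated
    with targeted GRAPPA kernels for single lines and adjacent pairs,
    with analytic and pseudo-multiple-replica g-factor noise-amplification
    maps.  Includes a multi-coil Cartesian k-space simulator with ground
    truth, POCS partial-Fourier reconstruction, and image-quality metrics
    (ghosting level, wall/lumen CNR, edge-profile acutance, voxel-wise T2
    fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
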