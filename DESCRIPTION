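Package: stenoscan
Title: Vessel Stenosis Quantification from Sequential B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates stenosed-vessel ultrasound phantoms, segments vessel
    cross-sections with a greedy active-contour model (snake) refined by
    sub-pixel radial profile fitting, plans circle and linear scan paths from
    marked fistula sites, reconstructs rotated contour stacks into 3D vessel
    models, and quantifies the degree of stenosis (DOS = 1 - d^2/D^2) with
    severity classification and method-agreement statistics. Designed for
    phantom-based validation of robotic arteriovenous-fistula ultrasound
    assessment pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    mgcv,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
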