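Package: hifucover
Title: Predicting Target Volume Coverage for MR-Guided Focused Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the fraction of a pelvic target volume that an
    MR-guided high-intensity focused ultrasound (MRgHIFU) treatment cell can
    reach. Models a Sonalleve-V2-class phased-array transducer and couch,
    ray-traces the discretized acoustic beam against voxel label maps of bone,
    extracorporeal air and organs at risk, sweeps the transducer exhaustively
    over its mechanical pose space, and reports target volume coverage (TVC)
    metrics. Includes landmark-based affine registration of supine referral
    imaging into the treatment orientation, automatic Otsu-based body-outline
    and coupling-air segmentation, deformation-aware estimation of the
    transducer home position from the skin surface, segmentation quality
    metrics (Dice, mean contour distance), and a deterministic digital pelvis
    phantom generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
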