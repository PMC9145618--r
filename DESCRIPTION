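Package: aroi
Title: Adaptive Region-of-Interest Compression for 3D CT Angiography Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hybrid lossless/lossy compression of 3D CT series driven by
    clinical regions of interest. Each slice is partitioned into a primary
    region of interest (the contrast-enhanced arterial tree plus a safety
    margin, compressed losslessly), a secondary region of interest (remaining
    body tissue, compressed with a rate-controlled lossy wavelet coder), and
    background (compressed heavily). A variable-bit-rate controller keeps
    every reconstructed slice above a configurable PSNR floor (default 40 dB);
    a fixed-rate variant uses the mean of the variable schedule. Includes a
    synthetic CT-angiography phantom generator with ground-truth masks, a
    minimal DICOM series reader/writer, a self-describing container format,
    and PSNR/MSE/compression-ratio evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
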