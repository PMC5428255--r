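Package: atsalign
Title: Automatic Time-Shift Alignment of Chromatographic Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aligns retention-time shifts across one-dimensional
    chromatographic fingerprints (GC-FID, HPLC-DAD single channel and
    similar uniformly sampled signals). Implements automatic time-shift
    alignment (ATSA): baseline-drift removal by robust filtering of local
    minimum values, multi-scale peak detection, segment-wise preliminary
    alignment driven by a peak-area-weighted total peak correlation
    criterion with robust repair of misaligned segments, and a
    peak-anchored precise alignment stage. Ships a reference correlation
    optimized warping (COW) implementation for benchmarking, a
    ground-truth synthetic chromatogram generator, and quality-control
    reports on correlation and peak-area preservation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
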