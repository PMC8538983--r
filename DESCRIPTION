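Package: thzrecon
Title: Hybrid Sparsity Reconstruction of Sparsely Sampled Raster-Scan Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs 2-D grayscale images from a random subset of
    raster-scan pixel measurements, as acquired by sparse terahertz
    time-domain spectroscopy scans. Combines a weighted exponential
    shift-invariant (undecimated) wavelet sparsity prior with a nonlocal
    self-similarity prior expressed as sparsity of block-matched patch
    groups under an orthogonal separable 3-D transform, and solves the
    resulting model with a split Bregman iteration whose quadratic
    subproblem is an exact diagonal solve. Includes a wavelet-only single
    sparse constraint baseline, PSNR and relative L2 norm error metrics, a
    synthetic seed-like phantom generator, sampling-rate sweep benchmarks,
    and a command-line interface for simulating acquisitions and running
    reconstructions.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
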