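# thzrecon

Reconstruction of 2-D grayscale images from **sparse random raster-scan
measurements**, as produced by terahertz time-domain spectroscopy (THz-TDS)
scanners that visit only a random subset of pixel positions to cut
acquisition time. Given measurements `y = R x` — where `R` is an M×N
row-selection matrix with a single 1 per row at a measured pixel — the
package estimates the full image `x` by solving a hybrid sparsity model:

```
min_x  Σ_p ‖Ψ_p^3D x‖₁  +  ‖W Ψ_e x‖₁  +  (μ/2) ‖R x − y‖₂²
```

* `Ψ_e` — a **tight-frame undecimated (shift-invariant) wavelet** analysis
  followed by an optional exponential reparameterization
  `(a^m − 1)/(a − 1)` of magnitudes normalized to [0, 1], which suppresses
  small coefficients and sharpens sparsity (`a = 10` by default).
* `W` — optional diagonal weights `w_n = 1/(|r_e,n| + δ)` inversely
  proportional to coefficient magnitudes (reweighted L1, `δ = 1e-5`).
* `Ψ_p^3D` — the **nonlocal self-similarity** operator: for every 8×8
  reference patch on a stride-4 grid, its 10 best-matching patches inside
  a 40×40 search window are stacked into an 8×8×10 block and transformed
  by a separable orthonormal 3-D transform (2-D DCT per patch face, 1-D
  DCT/Haar along the similarity axis).

The model is solved by a **split Bregman iteration**: because `RᵀR` is a
0/1 diagonal, the wavelet frame is tight (`ΨᵀΨ = I`) and the 3-D transform
is orthonormal, the quadratic x-subproblem is an exact elementwise
division; the two sparsity subproblems are (weighted) soft-thresholding;
Bregman variables accumulate the split residuals. A wavelet-only
single-sparse-constraint baseline (SSC) is the degenerate configuration
`γ = 0`, identity exponential, uniform weights.

The package is aimed at imaging researchers who want to benchmark sparse
raster-scan reconstruction without access to a scanner: it includes a
synthetic seed-like phantom generator, PSNR / RLNE metrics, a
sampling-rate sweep benchmark, file formats for masks and measurements,
and a command-line interface.

## Worked example

```r
library(thzrecon)

ph   <- seedPhantom(c(64, 64), seed = 1)      # synthetic seed-like object
ref  <- phantomImage(ph)
mask <- randomMask(c(64, 64), rate = 0.3, seed = 2)   # 30% of pixels
y    <- measure(ref, mask)                    # the sparse raster scan

rec  <- reconstructHSM(y, mask)               # hybrid model
ssc  <- reconstructSSC(y, mask)               # wavelet-only baseline

c(hsm = psnr(ref, reconImage(rec)), ssc = psnr(ref, reconImage(ssc)))
#>      hsm      ssc
#> 24.78930 23.44392
c(hsm = rlne(ref, reconImage(rec)), ssc = rlne(ref, reconImage(ssc)))
#>       hsm       ssc
#> 0.1795046 0.2095775
```

At a 30% sampling rate the hybrid model reconstructs the phantom about
1.3 dB better (PSNR) and with ~14% lower relative L2 error (RLNE) than
the wavelet-only baseline; the gap widens at lower rates. PSNR uses the
maximum of the reference image as its peak value, and
`RLNE = ‖x − x̂‖₂/‖x‖₂`.

`reconDiagnostics(rec)` exposes per-iteration data residuals, split
constraint residuals, relative change and the objective surrogate.

## Command line

```sh
thzrecon simulate    --out run/ --shape 64x64 --rate 0.3 --seed 1
thzrecon reconstruct --measurements run/measurements.csv --out run/ --method hsm
thzrecon evaluate    --reference run/reference.tif --estimate run/recon.tif --out run/
thzrecon sweep       --out sweep/ --config sweep.yaml
```

Each command writes a JSON manifest (config echo, paths, seeds, version)
so runs are reproducible bit-for-bit.

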