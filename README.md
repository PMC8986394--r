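# lrdenoise

Low-rank + sparse matrix decomposition for denoising 2-D grayscale images,
MRI slices in particular.

MRI slices are well approximated by low-rank matrices: rows and columns of
anatomical images are strongly correlated, so most of the signal energy sits
in a few singular vectors, while scanner noise and artefacts do not share
that structure. `lrdenoise` models an observed image `S` as

    S = R + H

with `R` the clean, low-rank image and `H` the noise, and recovers the pair
by robust principal component analysis (RPCA), i.e. the convex program

    min_{R,H}  α‖H‖₁ + ‖R‖₊   s.t.  S = R + H

where `‖R‖₊` is the nuclear norm (sum of singular values, the convex
surrogate for rank), `‖H‖₁` promotes sparsity of the noise, and `α > 0`
balances the two (default `1/√max(A,B)` for an `A×B` image). The program is
solved by an inexact augmented Lagrange multiplier scheme alternating
singular value thresholding on `R`, elementwise soft thresholding on `H`,
and a dual update. For low, dense noise a truncated-PCA path returns the
best rank-r approximation instead. A non-local-means (NLM) baseline, MSE /
PSNR metrics (`PSNR = 10·log₁₀(L²/MSE)` dB), a seeded phantom simulator
with exact ground truth, and PNG/NIfTI I/O round out the pipeline.

Intended users: image-analysis researchers who need a transparent,
ground-truth-validated denoiser and evaluation harness rather than a black
box.

## Worked example

```r
library(lrdenoise)

# a 128x128 exactly rank-5 phantom, 5% of pixels hit by +/-127.5 impulses
clean <- generate_phantom(phantom_spec(128, 128, "lowrank", rank_r = 5, seed = 1))
noisy <- add_noise(clean, noise_model(impulse_fraction = 0.05,
                                      impulse_amplitude = 127.5, seed = 1))

dec <- rpca_decompose(noisy)
dec
#> Low-rank + sparse decomposition (128 x 128)
#>   iterations: 18 (converged)
#>   relative residual ||S-R-H||_F/||S||_F: 9.77e-08
#>   objective alpha*||H||_1 + ||R||_*: 30812.6 (alpha = 0.08839)
#>   nonzero entries in sparse part: 819

tab <- run_compare(clean, noisy, methods = c("rpca", "nlm"), peak_L = 255)
format_compare(tab)
#> method            MSE   PSNR(dB)   peak L
#> noisy        812.6141    19.0320      255
#> rpca           0.0000   144.7107      255
#> nlm          446.0739    21.6367      255
```

The decomposition recovers the clean image to floating-point accuracy (MSE
~1e-10, hence the ~145 dB PSNR): the 819 nonzero entries of the sparse part
are exactly the corrupted pixels (5% of 16384 = 819). NLM, which averages
patches rather than exploiting the global low-rank structure, only smooths
the impulses.

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lrdenoise", package = "lrdenoise"))')
$CLI simulate --kind lowrank --size 128x128 --rank 5 --impulse-frac 0.05 --seed 1 out/
$CLI denoise --method rpca out/noisy.png out/denoised.png
$CLI evaluate out/clean.png out/denoised.png
$CLI compare --clean out/clean.png --noisy out/noisy.png --methods rpca,nlm out/
```

Images are plain numeric matrices indexed `(row, column)`; PNG values are
read onto the raw integer scale (0–255 or 0–65535) and clipped/rounded only
at write time.

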