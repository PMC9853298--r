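# csrfuse

Multimodal medical image fusion in R: block-DCT multiscale
decomposition plus convolutional sparse representation (CSR).

## What problem this solves

Structural scans (CT/MRI) show anatomy — edges, texture, contours.
Functional scans (PET/SPECT) show metabolism — smooth, bright uptake
regions, often pseudo-colored.  Clinicians reading both at once want a
single image that keeps the anatomy sharp *and* the uptake bright.
Plain averaging dims contrast; patch-based sparse-coding fusion leaves
blocky inconsistencies.  `csrfuse` is for researchers in medical image
analysis who need a reproducible, testable implementation of a
CSR-based fusion pipeline together with the standard objective quality
metrics used to evaluate one.

## The method

For registered sources $A$ and $B$:

1. **Decompose** each source with the orthonormal 8×8 block DCT into a
   low band and $l \le 3$ scales × 3 orientations of high bands
   (zig-zag partition of the 64 block coefficients); the sub-images
   sum back to the source exactly.
2. **Learn** a convolutional sparse sub-dictionary per scale by ADMM,

   $$\min_{d,x} \tfrac12 \sum_m \big\lVert y_m - \sum_k d_k * x_{m,k}
     \big\rVert_2^2 + \lambda \sum_{m,k}\lVert x_{m,k}\rVert_1,
     \quad \lVert d_k\rVert_2 = 1,$$

   with $D_h = [D_1, D_2, D_3]$ and a separate low-band dictionary
   $D_l$.
3. **Code** every sub-band with TV-regularized convolutional sparse
   coding,
   $\tfrac12\lVert s - \sum_k d_k * x_k\rVert^2
   + \lambda\sum_k\lVert x_k\rVert_1 + \lambda_1\,TV(\sum_k d_k * x_k)$.
4. **Fuse** per pixel by winner-take-all on whole coefficient vectors:
   low band by *region energy × averaged-L1 activity* salience, high
   bands by *sum-modified spatial frequency (NMSF) × activity*.
5. **Reconstruct** the fused sub-bands through the dictionaries and sum.

A fast transform-domain mode (`mode = "dct"`) fuses the low band by
uniform averaging and the high bands by maximum regional-deviation
weight.  Quality metrics: MI, SF, SD, RMSE, GSM, AG, EI.  A seeded
phantom generator produces registered structural/functional pairs with
ground-truth provenance masks for end-to-end testing.

## Worked example

```r
library(csrfuse)

pair <- make_pair(phantom_spec(size = 128, seed = 1))
cfg  <- fusion_config(mode = "csr", K = 8, max_iters = 20,
                      csc_iters = 120, seed = 1)
fz   <- fuse_pair(pair$structural, pair$functional, cfg)
fz
#> <csr_fusion> 128x128, mode=csr, clipped 0.641% of pixels

metric_report(fz$fused, pair$structural, pair$functional)
#> Fusion quality metrics:
#>   MI    5.516780
#>   SF    0.169819
#>   SD    0.313478
#>   RMSE  0.192063
#>   GSM   0.740190
#>   AG    0.040208
#>   EI    0.404711

audit_selection(fz, pair$masks)
#> $structural_accuracy  1.000  (textured anatomy won by the structural source)
#> $functional_accuracy  0.888  (uptake blobs won by the functional source)
```

Reading the numbers: MI is in bits (higher = more source information
retained); SF/SD/AG/EI are on the [0, 1] intensity scale (higher =
sharper/more contrast); RMSE is the mean distance to the two sources —
a *fused* image of genuinely complementary inputs sits between them,
so 0.19 here reflects the sources' own disagreement, not an error; GSM
of 0.74 says the fused gradients track whichever source has structure
at each pixel.  The fused image keeps 98.4% of the best source's
spatial frequency.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/csrfuse make-phantoms --outdir pair --size 128 --seed 1
Rscript inst/cli/csrfuse fuse --a pair/structural.png \
        --b pair/functional.png --out fused.tif --K 8 --seed 1
Rscript inst/cli/csrfuse evaluate --fused fused.tif \
        --a pair/structural.png --b pair/functional.png --out report.json
```

Every run writes a JSON manifest (command, config, seed, input
checksums, timing) beside its outputs.

## Documentation

The methods vignette (`vignettes/csrfuse-methods.Rmd`) describes the
model, the ADMM solvers and their numerical choices, the fusion rules,
what the phantom generator does and does not emulate, and known
limitations.
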