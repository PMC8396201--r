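# ectrecon

Iterative image reconstruction for 2D emission computed tomography (PET and
SPECT), for researchers studying regularised variants of the classic MLEM
algorithm and for anyone needing a self-contained, fully testable
reconstruction sandbox: sparse ray-traced projector, Poisson sinogram
simulator, procedural activity phantoms, reconstruction algorithms, and
quality metrics, all in plain R.

## The method

Detected counts `n(j)` per sinogram bin are independent Poisson variables
with means given by the linear forward model `ŷ(j) = Σᵢ x(i) p(i,j)`, where
`p(i,j)` is the intersection length of bin `j`'s ray with pixel `i`. MLEM
maximises the Poisson likelihood by the multiplicative update

    x⁽ⁿ⁺¹⁾(i) = x⁽ⁿ⁾(i)/s(i) · Σⱼ p(i,j) · n(j) / ŷ⁽ⁿ⁾(j),   s(i) = Σⱼ p(i,j)

which is monotone in likelihood and conserves counts exactly — but fits
noise as iterations grow. The package's centrepiece, **f-MLEM**, interleaves
a Beltrami geometric-flow denoising pass after each update: the image is
treated as a surface whose area the flow shrinks,

    xᵏ = xᵏ⁻¹ + hₜ · [x₁₁(1+x₂²) + x₂₂(1+x₁²) − 2x₁x₂x₁₂] / (1+x₁²+x₂²)²

so flat regions are smoothed aggressively while the `1/g` metric factor
preserves edges. The filter depth `K(n)` starts at `K0 = 10` inner steps and
decays linearly to zero over the outer iterations: heavy smoothing while the
estimate is noisy, none once structure has converged. See
`vignettes/fmlem-reconstruction.Rmd` for the full account.

## Worked example

```r
library(ectrecon)

geom  <- ect_geometry(n_angles = 48, n_bins = 64, image_shape = 64)
model <- build_system_model(geom)
truth <- make_brain_phantom(64)
sino  <- simulate_sinogram(truth, model, noise_config(1e5, 0.30, seed = 7))

cfg      <- mlem_config(n_iter = 40)
tr_mlem  <- mlem(sino, model, cfg, truth = truth)
tr_fmlem <- f_mlem(sino, model, cfg,
                   sched = fmlem_schedule(K0 = 10, h_t = 0.1), truth = truth)

glance(tr_mlem)
#> # A tibble: 1 × 6
#>   algorithm n_iter final_loglik final_df final_snr_db total_clipped_pixels
#>   <chr>      <int>        <dbl>    <dbl>        <dbl>                <dbl>
#> 1 mlem          40      368302.    0.462         6.05                    0
glance(tr_fmlem)
#> # A tibble: 1 × 6
#>   algorithm n_iter final_loglik final_df final_snr_db total_clipped_pixels
#>   <chr>      <int>        <dbl>    <dbl>        <dbl>                <dbl>
#> 1 f_mlem        40      367326.    0.373         6.89                    0
```

After 40 iterations on a 64×64 brain-like phantom (100 k true events, 30%
uniform background), f-MLEM reaches a lower relative norm error (`df` 0.37
vs 0.46) and a higher SNR (6.9 dB vs 6.1 dB) than plain MLEM on the same
sinogram — the filtered variant suppresses the noise MLEM amplifies while
keeping tumor edges. `tidy()` returns the full per-iteration table and
`autoplot(tr_mlem, metric = "snr_db", tr_fmlem)` draws the two curves.

A command-line wrapper covering each pipeline stage
(`phantom`, `simulate`, `filter`, `reconstruct`, `evaluate`, `benchmark`)
is installed at `inst/cli/ectrecon.R`:

```sh
Rscript inst/cli/ectrecon.R phantom --kind brain --size 192 --out phantom.csv
Rscript inst/cli/ectrecon.R simulate --phantom phantom.csv --counts 5e5 --seed 1 --out sino.csv
```

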