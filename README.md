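# metamerscale

Tools for asking whether a foveated *pooling-statistic* model of
peripheral vision produces **visual metamers** — physically different
images that observers cannot tell apart — and for estimating the
**critical scale** at which it fails.

## The scientific problem

Summary-statistic theories of peripheral vision hold that the visual
system compresses the periphery into texture-like statistics pooled over
regions that grow linearly with retinal eccentricity. A pooling model is
characterized by its *scale factor*

```
s = pooling-region diameter / eccentricity
```

If the model captures what the visual system retains, images synthesized
to match the model's pooled statistics should be indistinguishable from
the originals. The largest scale at which this holds for an image *I* is
its critical scale `s_crit(I)`, and the binding constraint for the theory
is the minimum over images, `s_system = min_I s_crit(I)`.

Discriminability is measured in a three-alternative oddity task and
modeled as

```
d'(s) = alpha * (1 - s_c^2 / s^2)   for s > s_c,   0 otherwise
p(correct) = 1/m + (1 - 1/m) * (1 - exp(-(d'/lambda)^k)),  m = 3
```

where `s_c` is the critical scale, `alpha` the asymptotic sensitivity
(gain), and `(lambda, k)` a Weibull link calibrated by Monte-Carlo
simulation of the ideal oddity observer. Critical scale and gain are
estimated on the log scale in a hierarchical Bayesian binomial model with
fixed effects of image type (scene-like vs texture-like) and comparison
(original-vs-synthesis vs synthesis-vs-synthesis), and random effects of
participant and image.

The package implements the full chain:

* **imageprep** — center-crop, grayscale, area-resample; standardize to
  mean gray 0.5 and RMS contrast sigma/mu = 0.3; plain-text PGM I/O.
* **pooling** — hard radial/angular partitions of the image annulus (32
  angular x 28 radial regions by default) with geometric radial spacing,
  so the diameter/eccentricity ratio is constant across rings.
* **synthesis** — pooled feature statistics through a self-contained
  oriented filter-bank backend with exact analytic gradients, image
  synthesis by monotone quasi-Newton descent, the normalized-MSE quality
  metric, and localized Gram-matrix texture distortions blended through a
  raised-cosine window.
* **oddity_link** — the Monte-Carlo oddity observer and the Weibull link
  calibration.
* **inference** — the hierarchical model, sampled by an adaptive
  Metropolis-within-Gibbs chain (C++), with split-chain Rhat diagnostics,
  posterior contrasts, and image-level `s_crit(I)` / `s_system`.
* **synthdata** — procedural scene-like/texture-like images and simulated
  observers with known ground truth for end-to-end recovery tests.
* **trials** — trial filtering (no-response, fixation breaks), binomial
  aggregation, and observer-mean descriptive statistics.

## Worked example

Simulate observers at the regime the method is designed for (scene
critical scale 0.22, texture 0.36 against originals) and recover the
parameters:

```r
library(metamerscale)

link   <- calibrate_link(seed = 1)           # Monte-Carlo Weibull link
link
#> <link_params> m = 3, lambda = 2.8402, k = 1.8566

gp     <- generating_params(seed = 11)       # 8 observers, 20 images
trials <- gen_trials(gp, link)
post   <- fit_critical_scale(trials, link, chains = 4,
                             iter = 2000, warmup = 1000, seed = 21)

for (ty in c("scene", "texture")) {
  ps <- population_scale(post, ty, "orig_vs_synth")
  cat(sprintf("%-8s s_c = %.3f, 95%% CI [%.3f, %.3f]\n",
              ty, ps$mean, ps$lower, ps$upper))
}
#> scene    s_c = 0.226, 95% CI [0.194, 0.264]
#> texture  s_c = 0.312, 95% CI [0.265, 0.363]

critical_scale_difference(post, "orig_vs_synth")
#> texture - scene difference = 0.086 [0.031, 0.145], p(diff<0) = 0.0015

image_critical_scales(post)$s_system
#>       comparison image_type  s_system     image
#> 1  orig_vs_synth      scene 0.1916990   scene08
#> ...
```

The estimates bracket the generating truths (0.22 / 0.36); the
scene-vs-texture difference is detected (`p(diff<0)` far below 0.05); and
the system critical scale is pulled below the population mean by the
image with the smallest realized critical scale.

Synthesis example:

```r
img    <- gen_image(128, "texture_like", seed = 5)
grid   <- build_polar_grid(128, n_angular = 8, n_radial = 6, inner_radius = 16)
bk     <- filterbank_backend(input_sizes = 128)
stats  <- pool_statistics(img, grid, bk)
synth  <- synthesize_pooled(stats, img, grid, bk, n_steps = 200,
                            pinned_radius = 16, seed = 9)
tail(attr(synth, "loss"), 1) / attr(synth, "loss")[1]   # ~5e-4
```

## Command line

A thin CLI ships in `inst/cli/metamerscale`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/metamerscale", package="metamerscale"))')" \
    genimg --kind texture_like --side 256 --seed 5 --out t.pgm
```

Subcommands: `prep`, `genimg`, `simulate`, `calibrate-link`, `process`,
`fit`, `synth`, `distort`.
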