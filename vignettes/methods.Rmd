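---
title: "Models, numerics and design choices in metamerscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in metamerscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the psychophysical model, the image-processing conventions, the numerical
choices, and — importantly — what the synthetic-data tests do and do not
establish.

## 1. The psychometric model

The package targets the question of whether an eccentricity-scaled
pooling model produces visual metamers. Sensitivity to the difference
between a reference image and a synthesis at pooling scale factor $s$
(region diameter over eccentricity) is modeled with the two-parameter
critical-scale function

$$ d'(s) = \begin{cases} \alpha\,(1 - s_c^2/s^2), & s > s_c \\
0, & s \le s_c, \end{cases} $$

with critical scale $s_c$ (below it the observer is at chance — the
metamerism plateau) and gain $\alpha$ (asymptotic $d'$ as $s \to
\infty$). The function is continuous at $s_c$ and non-decreasing.

$d'$ maps to proportion correct in the $m$-alternative oddity task
through a Weibull link,

$$ p(d') = \tfrac1m + \left(1 - \tfrac1m\right)
\left(1 - e^{-(d'/\lambda)^k}\right), \qquad m = 3 .$$

$\lambda$ and $k$ are **not** free parameters: they are fixed by
calibrating against a Monte-Carlo simulation of the unbiased ideal
oddity observer (`simulate_oddity_pc()`): two draws from a unit normal,
one shifted by $d'$; the observer picks the observation farthest from
the mean of the other two. `calibrate_link()` minimizes the summed
squared difference between the Weibull and the simulated psychometric
function over a default grid $d' \in [0, 6]$ in steps of 0.25 with
$10^5$ triads per point. With the default settings the calibration
yields $\lambda \approx 2.84$, $k \approx 1.86$ (the package derives
these at run time; they are quoted here only for orientation). The
decision rule sits behind a `simulator`/`rule` seam so alternative
observers can be swapped in; the closed-loop test feeds the calibrator
data generated from a known Weibull and requires recovery within 2%.

## 2. Hierarchical inference

`fit_critical_scale()` estimates $\log s_c$ and $\log \alpha$ in a
binomial nonlinear mixed-effects model: population intercept, fixed
effects of image type and comparison (with interaction, so each of the
four condition cells has its own level), a participant offset for each
participant × condition cell (participants crossed with both factors),
and an image offset for each image × comparison (images are nested in
type, so type is implied). Offsets apply to both parameters and are
mutually independent — the source description leaves the random-effects
placement partly open, and this symmetric choice is recorded here rather
than asserted as the original authors' coding.

Priors: $\log s_c$ intercept $\mathcal N(-0.69, 1)$ (centered on a
critical scale of about 0.5, the classic V2-scaling result); $\log
\alpha$ intercept $\mathcal N(1, 1)$; all other fixed effects $\mathcal
N(0, 0.5)$; group-level standard deviations half-Cauchy with location 0
and scale 0.1 (the phrase "mean 0 and sd 0.1" cannot describe a Cauchy
literally, so it is read as location/scale). Random effects are
non-centered ($z \sim \mathcal N(0,1)$ scaled by the group sd), which is
mathematically identical and samples far better.

### Why a purpose-written sampler

No MCMC engine (Stan, JAGS, PyMC) is available in the supported
environment, so the model is sampled by an adaptive
Metropolis-within-Gibbs chain written in C++: one random-walk update per
scalar parameter per iteration, with step sizes adapted toward 0.44
acceptance during warmup and frozen afterward. Two extra move families
are mixed in, both likelihood-invariant (they change parameters along
directions that leave every cell's linear predictor unchanged, so only
priors enter the acceptance ratio):

* **translation** — shift a fixed effect and absorb it into the $z$'s of
  the groups it touches; breaks the strong posterior correlation between
  a fixed effect and the mean of its random effects;
* **scaling** — multiply a group's $z$ vector by $e^{-\epsilon}$ while
  adding $\epsilon$ to its log-sd; the classic funnel direction.

Both are valid Metropolis-Hastings moves (the scaling move carries the
log-Jacobian $-n_g\epsilon$). On the default synthetic design they cut
the worst split-chain Rhat at 4 × 2000 iterations from ≈1.28 to ≈1.2
and halve run time relative to longer plain chains; at the full
4 × 20 000 regime Rhat is comfortably below 1.01. `fit_critical_scale()`
warns (with the maximum) whenever any parameter exceeds 1.01.

The default MCMC regime is 4 chains × 20 000 iterations with 10 000
warmup (40 000 post-warmup draws); tests and examples use reduced chains
and say so. Convergence is the split-chain potential-scale-reduction
statistic computed for every parameter.

Rows whose model has no scale covariate (the CNN-pooling comparison
model, plotted at an arbitrary abscissa in the source work) are dropped
from the fit with a message rather than fitted as an intercept-only
cell: without a scale they cannot inform $s_c$ or $\alpha$, and their
proportion correct is served descriptively by `pc_by_condition()`.

### Degenerate data

When every cell is at chance, two explanations compete in the posterior:
$s_c$ above the tested range, or $\alpha \approx 0$. Both get posterior
mass under the stated priors, so the posterior for $s_c$ shifts strongly
upward (mass above the largest tested scale grows to ≈2.5× its prior
share, and essentially none remains below the smallest tested scale) but
does not *concentrate* above the range. The tests assert the behavior
the model actually has.

## 3. Image standardization and geometry

Images are center-cropped, converted to grayscale by an unweighted
channel mean, and downsampled by exact area averaging (mean-preserving,
antialiased); the grayscale weights and resampling kernel are
conventions recorded here, not inferred intent. `standardize()` applies
the affine map to mean gray 0.5 and RMS contrast $\sigma/\mu = 0.3$
using the *population* standard deviation, so the moment contract holds
to $10^{-9}$ and the map is idempotent. Out-of-range pixels are **not**
clipped (clipping would break the exact moments); clipping happens only
at export, where `write_pgm()` returns the clipped fraction. Because no
PNG/TIFF reader exists in the supported R environment, file I/O uses the
plain-text PGM format plus CSV; the contract (integer-range mapping with
clipping) is unchanged.

The pooling grid divides the annulus between an inner (protected foveal)
radius and the image corner into `n_angular` × `n_radial` hard binary
regions — 32 × 28 = 896 above an inner radius of 64 px at 512 px by
default. The radial spacing is not stated in the source description;
geometric (log) spacing is the default because it makes
diameter/eccentricity constant across rings — with edge ratio $\rho$,
every ring has $s = 2(\rho-1)/(\rho+1)$ — which is the defining property
of an eccentricity-scaled model. Linear spacing is available behind
`spacing = "linear"` for comparison. Pixel centers sit at 0-based
integer coordinates, fixation at $((\mathrm{side}-1)/2,
(\mathrm{side}-1)/2)$; angular bin 0 starts at the positive $x$-axis,
counterclockwise. Smooth overlapping pooling windows (as in the original
foveated texture model, whose released code the source work ran) are
deliberately out of scope; only the scale-factor semantics and the
normalized-MSE loss metric are re-implemented.

For experiment-geometry conversions note that display stimuli were
upsampled ×2, so a 512 px raster viewed at ≈40 display px/deg has an
effective raster resolution of 20 px/deg; raster operations always work
in raster px and degree conversions are explicit via `px_per_deg`.

## 4. Synthesis numerics

The default feature backend is a self-contained multi-scale oriented
filter bank: four dyadic scales × four orientations of even, zero-mean
Gabor kernels plus a Gaussian lowpass, halfwave-rectified. Each scale is
exposed as a "layer" so per-layer Gram matrices parallel the ascending
layers of a deep texture network without any pretrained weights (a
pretrained backend would plug in behind the same `forward`/`vjp`
interface, but none ships: no deep-learning runtime exists in the
supported environment). Convolution is circular via FFT; gradients are
exact vector-Jacobian products and are checked against central finite
differences to a relative error below $10^{-3}$.

`pool_statistics()` resamples the image to each backend input size (128,
256, 512 by default), computes features at that size, and averages each
channel within each region. Feature maps are produced at the full raster
of each size, so no mask/feature alignment step is needed. The loss for
synthesis is the unweighted sum over input sizes of the mean squared
statistic difference — the size weighting is unstated in the source
description and is config-exposed by passing a grid subset.

The optimizer is Barzilai–Borwein gradient descent with Armijo
backtracking: a quasi-Newton-scaled step accepted only on sufficient
objective decrease, so the reported loss trace is non-increasing by
construction. Initialization is Gaussian noise matched to the original's
mean and sd outside a pinned central disk. Whether the central region
was merely initialized or held fixed is ambiguous in the source
description ("starting from Gaussian noise outside the central region");
the default **pins** it (`pin = TRUE`), which is the stricter reading,
and a switch provides the other. Stopping: `n_steps` or relative loss
change below $10^{-9}$.

Local distortions match per-layer Gram matrices — channel × channel
inner products over the analysis patch divided by its pixel count (the
normalization is unstated; this choice is recorded here) — over a square
of side $2(r + 24)$ for distortion radius $r$, then blend the resynthesis
into the original through a circular raised-cosine window ramping from 1
to 0 over the 12 px just inside radius $r$. Pixels at distance $\ge r$
are bitwise untouched.

## 5. The synthetic world

`gen_trials()` mirrors the inference model generatively. Its defaults
*are* the stated study regime: population critical scales 0.22 (scene) /
0.36 (texture) against originals and 0.28 / 0.37 between syntheses; 8
participants, 10 + 10 images, scale factors {0.25, 0.36, 0.46, 0.59,
0.7, 0.86, 1.09, 1.45}, 4 trials per cell. Where the source states no
value we chose once: gains 2.7 (orig-vs-synth) and 1.6 (synth-vs-synth)
in $d'$ units — the latter reflecting the reported poor asymptotic
performance when both stimuli are distorted — and random-effect sds of
0.10 (participant) and 0.15 (image) on the log scale, modest
heterogeneity of the size psychophysical group studies typically show.

`gen_image()` emulates the two content classes only coarsely:
texture-like images are stationary $1/f$-filtered noise; scene-like
images are sharp-edged polygons, long bars and explicit T-/L-junction
primitives clustered around a random focus (junction primitives are
included because junction density is the leading hypothesis for what
makes scene content hard to match). They reproduce the *statistical
signatures* the analysis keys on — homogeneous vs inhomogeneous local
structure — not natural-image statistics; a green synthesis or recovery
test therefore establishes that the machinery is correct, not that the
conclusions transfer to photographs.

Two statistical caveats on recovery tests. First, with truths at or
below the smallest tested scale (scene 0.22 vs minimum scale 0.25),
small designs are only bounded from above, not located, and the prior
(centered at 0.5) biases estimates upward — the same overestimation the
source work itself flags for its hardest images. The full default design
overcomes this; the small module-level test uses truths inside the
tested range. Second, with 10 images per type and image sd 0.15, the
realized image sample's mean deviates from the population truth by a few
percent; the 20% recovery tolerance absorbs both effects.

## 6. Known limitations

* The sampler is a random-walk scheme; it needs the full iteration
  budget for clean Rhat on weakly identified parameters (group sds under
  zero heterogeneity). A gradient-based sampler would mix faster.
* Circular convolution wraps image borders; for pooled statistics this
  contaminates only corner regions, but border-sensitive applications
  should pad.
* The filter-bank backend is a stand-in for a deep texture feature
  space; Gram matrices over 4-channel layers are far lower-dimensional
  than their CNN counterparts.
* The trial-filter pipeline reproduces the deposited-data bookkeeping
  (no-response then fixation-break, binomial aggregation) but the
  deposited archive itself is not fetched; the schema adapter in
  `read_trials_csv()` is the seam where its column dialect would map in.
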