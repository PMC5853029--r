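---
title: "How focusqc assesses absolute microscope focus quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How focusqc assesses absolute microscope focus quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automated microscopes acquire far more images than anyone can inspect, and
some fraction of them is out of focus despite hardware autofocus. Classical
focus metrics (variance, spectral slopes, correlation measures) only rank
images *relative to each other*: turning a ranking into in/out-of-focus
calls needs a user-chosen, channel-specific threshold, which rules out
unattended quality control. A second difficulty is that focus is only
defined where there is something to look at — most of a fluorescence image
is dark background.

`focusqc` addresses both issues the way modern high-content-screening QC
does: a small convolutional network classifies each 84 × 84 image patch
into one of 11 *absolute*, physically calibrated defocus levels (level
`L` ≙ `2·L` µm from best focus, blur diameters roughly 3–30 px), and an
entropy-based certainty downweights patches that carry no focus
information. No user parameters are needed at prediction time.

## Physics-based training data

Labeled out-of-focus images are rare; in-focus images are plentiful. The
package therefore *manufactures* labeled data by defocusing in-focus images
synthetically with a scalar diffraction model of a circular-aperture
objective:

$$h(x,y,z)=\left|C\int_0^1 J_0\!\Big(k\tfrac{NA}{n}r\rho\Big)
  \exp\!\Big(-\tfrac12 jk\rho^2 z\big(\tfrac{NA}{n}\big)^2\Big)
  \rho\,d\rho\right|^2$$

with `NA = 0.5`, `n = 1.0`, `λ = 500` nm, `k = 2π/λ`, evaluated at
`z = 0, 2, …, 20` µm (`compute_psf()`). At `z = 0` the integral collapses
to the Airy pattern `(2 J₁(v)/v)²` — the unit tests hold the quadrature to
that closed form. Kernels are normalized to unit sum, symmetric in `±z`,
and their 80%-energy diameter grows approximately linearly with `|z|`,
which is what makes the 11 levels perceptually evenly spaced.

Numerical choices: composite Simpson quadrature with 201 fixed nodes over
`ρ ∈ [0,1]` (doubling the nodes moves no kernel weight by more than 1e-6);
kernel radius `ceil(1.5 · z·NA/n / pixel_size) + 4` px so that tail
truncation is negligible (a warning fires if a user-chosen radius clips
more than 10% of the mass); convolution via FFT with *reflective* padding,
because zero padding would darken image borders and mimic defocus.

The camera pixel size is not an optical constant of the model but a
property of the instrument; the default 0.65 µm/px corresponds to a 6.5 µm
sensor pixel at 20× magnification with 2× binning and reproduces the
3–30 px blur range quoted above.

After blurring, sensor noise is applied (`apply_poisson_noise()`): counts
are converted to photoelectrons with the camera offset and gain
(`e = max(counts − offset, 0)/gain`), Poisson-sampled, and converted back,
clipped to the 16-bit range. The subtract-offset → Poisson → restore-offset
order is a modeling choice; only "accounting for offset and gain" is
physically prescribed.

## The synthetic scene generator

Every test in the package runs against seeded synthetic scenes
(`make_scene()`), not downloaded data: 520 × 696 fields of 80–160
nuclei-like blobs (radius 4–9 px, interior 3 000–12 000 counts) on a
100-count background, with sensor offset 50 and gain 2 — a well-exposed,
2×-binned nuclei channel.

Blobs are flat-top disks with a soft error-function edge (width 0.8 px)
rather than Gaussian bumps. This matters: a Gaussian profile is
band-limited, so a Gaussian-blob scene contains almost no high spatial
frequencies even in focus — there is nothing for defocus to remove, and
spectral focus metrics degenerate (we measured the PLLS slope *rising*
with defocus on Gaussian scenes because only the flat shot-noise floor
remains in the fit band). Real nuclei have sharp boundaries; the erf-edged
disk reproduces that broadband edge spectrum with one parameter.

What the generator does *not* emulate: chromatin texture, cell clumping,
uneven illumination, multiple channels, spatially varying focus within one
field, or real camera artifacts. Passing tests therefore demonstrate that
the pipeline recovers defocus under its own forward model — the same
"simulation-to-real transfer" caveat any synthetically trained model
carries — not performance on any particular instrument.

## The ordinal classifier

Architecture (fixed): conv 32@5×5 → 2×2 max-pool → conv 64@5×5 → 2×2
max-pool → FC 1024 → dropout 0.5 → FC 11 → softmax, on raw counts scaled
by 1/65535. Per-patch standardization is deliberately *not* applied: the
gain/offset augmentation (below) is supposed to teach brightness
invariance, and standardizing inputs would erase the very signal that
experiment probes.

The loss is the discrete ranked probability score
`RPS = Σᵢ (Pᵢ − Tᵢ)²` on cumulative distributions, not cross-entropy: a
one-hot prediction `d` levels from the truth costs exactly `d`, so the
loss respects the ordering of the classes.

Training samples a *freshly positioned* random 84 × 84 crop from a whole
stack image at every draw (`labeled_image_set`). This matters more than
any optimizer setting: in a diagnostic run trained on a fixed set of
pre-cut patches (8 crops per stack image) the 22M-parameter network
memorized them — 97% within-one accuracy on its training patches against
68% on held-out scenes — while fresh-crop training closes that gap
entirely. Training from a fixed `labeled_patch_set` remains supported for
small sanity runs.

Every sampled crop is then augmented with a random gain and offset,
log-uniform in (0.2, 5.0) and (1, 1000), clipped to 16 bits. Augmentation
is applied per *patch* draw (each revisit of a region sees a new gain and
offset), the finer-grained reading of an ambiguous prescription.

Desk-scale training (`desk_train_config()`): single worker, batch 32,
1 200 steps, Adam at 1.5e-3 with linear decay to 10% of the base rate.
The configuration was calibrated on the synthetic benchmark: a constant
high rate plateaus and then oscillates (held-out within-one accuracy
*fell* from 78% at 1 000 steps to 75% at 2 000 without decay), smaller
batches waste the fixed per-step cost (batch 16 for 2 000 steps reached
only 91%), and with decay the accuracy climbs from ~94% at 1 200 steps
(learning rate 1e-3) through ~96% (1.5e-3) to ~97% at 2 000 steps for
those with half an hour to spend. The reference regime — a million steps
across 64 replicas at a constant 5e-6 — is preserved in `train_config()`'s
defaults for completeness but is not a single-CPU proposition; shrinking
the step budget by three orders of magnitude requires a correspondingly
larger learning rate. Weights start from a fan-in-scaled truncated normal
(±2σ), biases at zero; the whole run is a pure function of the data and
one seed. The implementation is hand-written C++ (im2col + BLAS GEMM,
single precision) because no deep-learning runtime is assumed.

## Certainty and aggregation

For a softmax output `p` over `N = 11` levels,
`certainty = 1 − H(p)/log N` with `H` the Shannon entropy: 0 for a uniform
(uninformative) prediction, 1 for a one-hot one. Note the equation is the
*normalized complement* of the entropy — writing it without the minus sign
on `H`, as sometimes happens in print, would produce values above 1.
Certainty is permutation invariant: it measures peakedness, not location.

The whole-image distribution is the certainty-weighted average of the
patch distributions; empty background patches (certainty ≈ 0) contribute
nothing, so one sharp nucleus in a sparse field can carry the image call.
The "aggregate certainty" of an image is the certainty of that aggregate
distribution — kept on the same [0, 1] scale as the per-patch values so
the mean-vs-aggregate scatter (`certainty_scatter()`) is a square plot;
its corners separate consistent images, images with conflicting confident
patches, sparsely informative images, and empty ones. If *every* patch has
exactly zero certainty the aggregate falls back to the unweighted mean
with a warning (the 0/0 case is undefined).

Visualizations follow the same grammar everywhere: 11 evenly spaced hues
(level 0 anchored at red = best focus) for the predicted level, lightness
for certainty, drawn as patch borders (`annotate_image()`) or as an
11 × 10 level-by-certainty montage of sample patches
(`prediction_montage()`, last certainty bin right-closed so certainty 1.0
lands in the top bin).

## The PLLS baseline

The power log-log slope is the strongest classical competitor: the OLS
slope of log radial power spectral density vs log spatial frequency
(`radial_psd()` — mean-subtracted periodogram, radially binned, DC
excluded). Defocus removes high frequencies, so blurrier images have more
negative slopes; gain shifts only the intercept and offset is removed with
the mean, so the metric is photometrically invariant by construction.

The fit band defaults to 0.01–0.05 cycles/px. The band must sit below the
first zero of the defocus MTF at the *largest* level being graded (a 30 px
blur disk has that zero near `3.83/(π·30) ≈ 0.04` cycles/px): above it a
strongly defocused image's spectrum is flat shot noise, and a slope fitted
there saturates or reverses instead of tracking defocus. We verified this
directly — with a generic wide band (0.05–0.45) the slope *increases* with
defocus level on noisy synthetic stacks, with or without a Hann window,
while with the default band the slope orders all 11 levels essentially
perfectly (Spearman ρ ≈ −1 across seeds). The band (and an optional Hann
window, off by default since leakage proved immaterial here) remain
configurable. One residual caveat: between levels 9 and 10 the mean
whole-image slope can plateau — at the extreme level the band's top edge
touches the MTF zero — which is why the monotonicity checks are stated as
rank correlation rather than strict decrease at every step.

`plls_patchwise()` applies the metric inside the same 84 × 84 tiling as
the classifier and averages the finite per-tile slopes (certainty
weighting has no analogue for a scalar metric). With only ~3 usable
frequency bins per tile it is noticeably noisier than the whole-image
version — consistent with patch-level PLLS being the weaker variant.

## Evaluation harness

Two protocols mirror common practice:

* **Binary in/out-of-focus.** Images are ranked by a scalar score — for
  the classifier, the expected level `Σ i·pᵢ` under the aggregate
  distribution (the reduction is configurable: argmax level or
  `1 − p₀`) — a threshold is chosen on a random 10% validation split by
  maximizing the F-score (harmonic mean of precision and recall; ties to
  the lowest threshold; candidate thresholds are the midpoints between
  sorted validation scores), and precision/recall/F are reported on the
  remaining 90%. `select_threshold()` is tested against an exhaustive
  brute-force search. On synthetic stacks, levels {0, 1} count as in-focus
  and {2..10} as out-of-focus by default (human ratings don't exist for
  synthetic scenes); the split point is configurable.

* **Absolute defocus.** Confusion matrices over all 11 levels
  (`confusion()`), the within-one-level accuracy (`within_k_accuracy()`,
  `k = 1` ≈ a 3 px blur-diameter tolerance), and a gain/offset robustness
  grid (`robustness_grid()`) that re-evaluates a model on
  photometrically transformed test patches (gains {0.5, 1, 2}, offsets
  {0, 1000} by default, identity cell included). Evaluation restricts to
  *foreground* patches: a background patch is the same Poisson-noised
  constant at every defocus level, so its label is unlearnable in
  principle, and including it would only measure label noise.

## The self-contained benchmark

`run_defocus_study()` ties everything together: 24 synthetic scenes, split
50/50 into train/test *by scene* before any patch is cut (the synthetic
stand-in for splitting by imaging site — no scene leaks into both sides),
11-level stacks, fresh-crop training with augmentation on the training
half, and within-one-level accuracy on 8 random pre-cut crops per stack
image of the held-out foreground. These sizes are the package's
reference configuration for a single-CPU run of roughly a quarter hour;
`scripts/acceptance.R` re-runs exactly this study from scratch and
reports the accuracy.

Two deliberate departures of that benchmark from its full-scale
inspiration: training uses thousands rather than a million steps (see
above), and accuracy is measured per *patch*, which is strictly harder
than per image — aggregation over ~48 patches averages single-patch
mistakes away.

## Known limitations

* The scalar PSF model ignores vectorial high-NA effects, spherical
  aberration and depth-variant blur; it is adequate for NA ≤ ~0.7 air
  objectives, which is its intended regime.
* The classifier's absolute calibration is only as good as the optical
  parameters used to synthesize training data; a mismatch in pixel size
  or NA shifts the level scale.
* 16-bit PNG output is not supported by the installed PNG writer; TIFF is
  the lossless interchange format (PNG export is 8-bit, with a warning).
* Certainty is a property of the softmax distribution, not a calibrated
  probability; it separates informative from empty patches but is not a
  confidence interval.
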