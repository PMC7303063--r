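---
title: "A summary-statistic model of peripheral vision and a decision-complexity laboratory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A summary-statistic model of peripheral vision and a decision-complexity laboratory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveatex)
```

## The model

`foveatex` implements a texture-tiling account of peripheral vision.  The
core claim is that outside the fovea the visual system does not keep a
pixel-like image but a collection of *summary statistics*, each pooled
over a local region whose size grows linearly with eccentricity
$e$ (angular distance from fixation):

$$d(e) = \max(d_0, \; g\,e),$$

with a growth rate $g$ and a foveal floor $d_0$.  Within each pooling
region the image is summarized by a fixed roster of statistics computed
from a multi-scale oriented decomposition — the two-stage "filter,
pointwise multiply, then pool" computation of V1-like models.  Everything
downstream (what can be discriminated in the periphery, what a synthesized
"mongrel" looks like, how hard a search display is) follows from what this
encoding preserves and discards.

### The front end

`build_pyramid()` decomposes a luminance image into $S$ dyadic scales
$\times$ $O$ orientations of complex-valued subbands plus highpass and
lowpass residuals.  Filters are polar-separable in the frequency domain:
log-raised-cosine radial sections (one-octave transitions) and
$\cos^{O-1}$ angular sections, normalized so that squared responses sum to
one at every frequency.  The transform is therefore an exact tight frame:
`reconstruct_pyramid()` returns the input to machine precision, which the
synthesis loop depends on.  Bands are made complex (quadrature pairs) by
doubling the positive-frequency half-plane, so band magnitude and phase
are both defined.  Boundary handling is circular.

### The pooling lattice

`build_pooling_scheme()` tiles the visual field with a log-polar lattice:
a foveal disk of diameter $d_0$ and annular sectors whose radial windows
are raised-cosine-squared in $\log_2 e$ with 50% overlap (constant width
in log eccentricity is exactly linear growth in $e$), crossed with
raised-cosine-squared angular sectors.  Sectors default to 2:1 radial
elongation, the usual description of crowding zones.  Overlapping
cosine-squared windows at 50% spacing sum to one along each axis, and a
final pixelwise normalization makes the partition of unity exact, which is
what lets overlapping per-region adjustments be blended seamlessly during
synthesis.  Defaults are $g = 0.5$ (the rule-of-thumb size of crowding
zones) and $d_0 = 1^\circ$; both are exposed.
`uniform_pooling_scheme()` provides the degenerate single-region
configuration — classic homogeneous texture analysis/synthesis — used to
validate the statistical machinery independently of foveation.

### The statistics

Per region, `compute_region_stats()` computes (defaults $S=4$, $O=4$,
autocorrelation neighborhood $M=7$; 667 statistics, within the model's
nominal budget of about a thousand per region):

* luminance marginals: mean, variance, skewness, kurtosis, min, max;
* variances of the highpass residual and of each scale's lowpass band,
  and the mean and variance of each oriented band's magnitude (the raw
  pooled "pointwise multiply then average" moments);
* the central $M \times M$ normalized autocorrelation of the luminance
  image, of each lowpass band, and of each band's magnitude (one of each
  $\pm$ offset pair; the zero lag is identically one and not stored);
* magnitude cross-correlations between orientation pairs within a scale
  and between adjacent scales (the coarse band spectrally upsampled);
* the real-part correlation of each band with the phase-doubled upsampled
  coarser band (cross-scale phase alignment, which distinguishes edges
  from gratings).

All correlations are weighted by the region's pooling window and bounded
in $[-1, 1]$.  Two conventions keep statistic vectors comparable across
regions.  First, a *degenerate-variance rule*: any correlation involving a
(near) zero-variance signal is defined as 0 rather than NaN.  Second, a
*support-sufficiency rule*: a statistic estimated at a resolution where
the region retains fewer effective samples ($1/\sum w_i^2$) than the $M^2$
autocorrelation neighborhood would be dominated by sampling noise, so it
is defined as 0 (deterministically, for any input).  Regions clipped to
slivers by the image boundary otherwise contribute pure noise: two draws
of the same texture process can differ by several tenths in correlation
units on such regions, which would swamp every downstream comparison.

## Mongrel synthesis

`synthesize_mongrel()` produces an image with (approximately) the same
per-region statistics as a target but otherwise random — the metamer
machinery.  The optimizer is alternating projection, not gradient descent:
each iteration rebuilds the pyramid of the current image, projects band
magnitudes and the lowpass chain toward each region's targets (blending
overlapping regions with the partition-of-unity weights), reconstructs,
and imposes the marginal statistics in the pixel domain.  Numerical
choices that proved load-bearing:

* **Truncated-spectrum projection.**  Autocorrelation targets are imposed
  by a spectral gain $\sqrt{S_t/S_c}$ where $S_t, S_c$ are the spectra
  implied by the target and current truncated autocorrelations
  (Blackman–Tukey style), floored at 2% of their peak and clamped to
  $[1/3, 3]$ per pass.
* **Fresh measurements.**  Projections late in the pipeline measure their
  "current" statistic from the in-flight signal rather than from the
  start-of-iteration statistics; stale correction ratios compound across
  stages and caused seed-dependent divergence.
* **Ordering and protection.**  The range clip in the marginal stage
  injects broadband noise, so the highpass variance is imposed *after*
  the marginal remap (a spectral surgery), the luminance and chain
  spectral filters leave their top octave untouched, and every iteration
  ends with a refinement pass that re-projects the spectral statistics
  without re-running the marginal remap.
* **Steady-state compensation.**  The clip and the analytic-band
  constraint each revert a fraction of any imposed adjustment, leaving a
  persistent bias at equilibrium.  Working targets are therefore
  compensated integrally: multiplicative factors on the variance-family
  statistics and additive offsets (bounded at $\pm 0.25$) on the
  correlations adapt at rate 0.4 per iteration until the measured
  statistics sit on target.  Magnitude autocorrelations additionally use
  over-projection exponents that increase toward coarse scales, where
  reversion is strongest.

Convergence is reported per statistic group as a scaled RMS deviation:
correlations, skewness and kurtosis on their natural $O(1)$ scales,
luminance marginals relative to their own size with a floor of a tenth of
the luminance range, variances with small floors.  The default tolerance
is 5% per group within 50 iterations.  The fovea can be constrained to the
source pixels (the fovea is "seen"); `mongrel()` does so by default.

On a $128 \times 128$ binary noise texture (0.25° grain at 16 px/°,
whole-field pooling) synthesis converges in roughly 15–40 iterations, and
two seeds give images differing by ~0.5 RMS in pixel space while both
match the target statistics — a metamer pair.  A constant image is an
exact fixed point.  A pure grating is *not* recovered to fractional-percent
precision: the $M \times M$ truncated autocorrelations do not uniquely pin
a sinusoid, and the pixel-domain marginal remap keeps injecting weak
harmonics into otherwise silent bands, so the synthesis recovers the
grating's dominant orientation-energy structure (shares within 0.1,
variance within a few percent) but not its near-zero band energies at the
per-mille level.  This is a known limitation of the statistic roster, not
of the optimizer settings.

## Discriminability

`stat_distance()` is the z-scored Euclidean distance between two
encodings, with per-statistic scales supplied either directly or from
`stat_norm_ensemble()` (the standard deviation of each statistic over
seeded phase-scrambled variants of a reference image; zero-variance
statistics are dropped and counted).  It satisfies the metric axioms.

Two task-level predictors are built on top, and both required a decision
about what "discriminable" means for a deterministic encoder:

* `search_difficulty_proxy()` measures how separable target-present
  patches are from target-absent patches at a given eccentricity.  A
  naive distance between *matched* pairs (identical flankers, only the
  central item swapped) gets the paper's ordering backwards: it credits
  T-vs-L with every small deterministic difference while removing the
  flanker variability that constitutes crowding.  The proxy therefore
  draws the two patch classes independently (seeded flanker rotations and
  positional jitter), and reports the distance between class means in
  units of the pooled within-class standard deviation, debiased for
  sampling.  An orientation pop-out target then dwarfs a T among rotated
  Ls at 10° eccentricity — the direction the theory requires — with the
  T/L separation collapsing to zero under full crowding.
* `change_visibility()` scores each pooling region by its most diagnostic
  *single* statistic (largest absolute difference on the statistic's
  natural scale).  Summing across all ~670 statistics instead lets many
  tiny shifts in a large far region outvote the one large shift in a
  small near region and reverses the fixation-distance effect.  Note that
  the fixation-distance effect also needs clutter: on a sparse gray
  display, even a 2.5° region contains only the one changed square and
  encodes its luminance well, so the model honestly predicts little
  change blindness there.  The packaged demonstration therefore uses
  colored squares on a granular textured background
  (`stimulus_spec(background = "texture")`), the analogue of the
  photographic scenes used for such demonstrations.

## The decision-complexity laboratory

The second half of the package treats visual tasks as classification over
an encoding, with an explicit cap on decision-boundary complexity
(`complexity_budget()`): the number of linear hyperplanes, the number of
feature dimensions, or the boundary curvature (realized as an RBF kernel
bandwidth floor).  `fit_budgeted_classifier()` draws seeded samples from a
`task_spec()` and fits within the budget.  The hyperplane learner is a
greedy arrangement search with coordinate-ascent refinement and
majority-labeled cells; a plane is only retained if it improves training
accuracy by at least 0.2%, a complexity-control rule that also makes the
fitted models nested in the budget, so accuracy is monotone in $k$.  With
an unlimited budget the fit reaches the analytic Bayes accuracy on
Gaussian toys ($\Phi(\Delta/2)$) within sampling error; an XOR-arranged
task is capped near 75% with one hyperplane and solved with two.

`compose_tasks()` forms the product of two tasks (classes multiply:
two 2-alternative tasks become one 4-alternative dual task), and on a
fixed budget the composed task is never easier than its harder component.
`mot_hypothesis_count(n, k)` counts the $\binom{n}{k} - 1$ competing
hypotheses a tracking task must reject (125 when tracking 4 of 9).
`vwm_experiment()` measures how far a one-item change moves an encoder's
representation of a colored-square array as set size grows — the measured
direction is reported, not asserted, since it depends on the encoder —
and `scene_confusability()` generalizes the resulting precision to
arbitrary probe sets: which stimuli fall within the working-memory-derived
threshold of each other.

## What the synthetic stimuli do and do not cover

All test inputs are generated internally: stroke-font letter arrays,
search displays (orientation pop-out, T-among-L, conjunction), crowded
peripheral patches, colored-square arrays with change pairs, and seeded
noise textures with a controllable grain.  They are rendered analytically
(no system fonts), so identical specs and seeds give bit-identical images
on any platform.  They emulate the *geometry* of the classic displays —
eccentricity, spacing, set size, clutter — but not photometric calibration,
color opponency (the encoder is luminance-only by default; the statistic
roster is stated for luminance), or natural-scene content.  Passing tests
therefore demonstrate the internal consistency of encoder, synthesis and
predictors under controlled conditions, not quantitative agreement with
human thresholds on natural images.

## Problem sizes and defaults

The packaged analyses use sizes a laptop handles comfortably: 128×128
texture patches for synthesis (50-iteration budget), ~64–128 px stimulus
fields for discriminability with 10 seeded draws per condition, ensembles
of 100 phase scrambles for normalization, and classifier experiments with
hundreds of training and thousands of test samples.  All knobs (pyramid
depth, orientation count, neighborhood size, pooling growth rate, ensemble
sizes, iteration budgets) are function arguments with the defaults stated
above.

## Known limitations

* Color is collapsed to luminance before encoding; per-channel statistics
  are not implemented (the model's statistic list is stated for
  luminance).
* Synthesis quality degrades for pooling regions with few effective
  samples; the sufficiency rule zeroes (rather than estimates) their
  statistics, and foveated mongrels are best treated as qualitative
  visualizations.
* Gratings and other spectrally degenerate targets are recovered
  structurally, not to fractional-percent statistic error (see above).
* The discriminability predictors are explicit stand-ins: the reference
  account never specifies the computation behind its model-side
  discriminability axis, so only orderings across conditions are
  interpreted, never absolute values or reaction-time slopes.
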