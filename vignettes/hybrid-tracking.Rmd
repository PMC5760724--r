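---
title: "Hybrid single-particle tracking of dim fluorescent spots"
author: "dimtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid single-particle tracking of dim fluorescent spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimtrack)
```

## The problem

Single-molecule fluorescence movies — for example MS2-labelled mRNA imaged in
neuronal dendrites at 10 frames per second — often sit at signal-to-noise
ratios between 1 and 4, where fully automatic trackers fragment trajectories
and manual tracking of hundreds of frames is impractical. `dimtrack`
implements a hybrid strategy: each particle is annotated once in the first
frame, followed automatically frame by frame within a small scan region, and
every genuinely ambiguous frame (no spot bright enough, or two particles in
one scan region) is delegated to an *intervention policy*. The policy may be
a human at a console, a scripted decision table, a hands-off automatic rule,
or — for validation on synthetic data — an oracle that consults the
simulator's ground truth. Because the ambiguous frames are rare, a handful of
decisions buys trajectories that neither pure manual nor pure automatic
tracking delivers at this SNR.

## The tracking procedure

For each annotated particle and each frame:

1. **Scan region.** A `scan_rows` by `scan_cols` rectangle (odd sizes,
   typically 5–50 px) is centred on the particle's last localized position,
   rounded to the nearest pixel and clipped at the image border. After a gap
   frame the region stays where the particle was last seen; regions are not
   grown, which keeps the search local and cheap.
2. **Detection.** The mean intensity of every `window_size` square window
   that fits inside the region forms a window-mean map. Its local maxima are
   candidate spots; a candidate is accepted when its window mean exceeds the
   local background by more than `brightness_k` background standard
   deviations. Candidates closer than `min_separation` px to a brighter one
   are suppressed.
3. **Resolution.** Exactly one candidate → automatic sub-pixel localization
   (`status = "detected"`). No candidate → a `no_maximum` request: the policy
   answers `stop` (terminate the track), `manual` (supply a position), or
   `gap` (record `NaN`). Two or more candidates → an `overlap` request:
   `manual`, `pick_candidate`, or `linear_motion`, which extrapolates the
   velocity between the last two localized points and localizes around the
   predicted position (`status = "predicted"`).

### Detection threshold

The brightness criterion is a design choice of this package. The background
level is the **median** of the scan-region pixels outside the brightest
window, and the spread is the **scaled MAD** of the same pixels. Both must be
robust: during a two-particle encounter the second spot sits precisely in the
background annulus, and with a mean/SD estimate its bright pixels inflate the
threshold enough to extinguish all detections (we observed exactly this
failure with the non-robust variant). The default `brightness_k = 2` accepts
window means two (robust) standard deviations above background; at the
default 7-px window the window mean averages 49 pixels, so the effective
false-positive rate on pure noise is negligible while spots at SNR 2 are
still detected in the vast majority of frames.

### Overlap handling and the 1-px refinement gate

`linear_motion` answers the question "which spot is mine?" with "the one that
continues my velocity". The prediction seeds sub-pixel localization, but near
the closest approach the localization window inevitably catches light from
the second particle and the refined position can slide toward it. The engine
therefore accepts the refinement only if it stays within 1 px of the
prediction, otherwise the prediction itself is recorded. One pixel is well
above the localization noise of an isolated spot (≈ 0.05–0.1 px at SNR ≥ 5)
and well below the `min_separation` of distinguishable candidates, so the
gate is inert except when it is needed.

Two caveats are inherent to the problem, not to this implementation. First,
if two spots approach closer than roughly the window size, the window-mean
map has a single maximum and the engine sees an unambiguous detection of the
merged blob; no decision policy is consulted and no tracker — human-assisted
or not — can separate identities inside the blob. Our crossing fixtures
therefore let trajectories cross in x while passing ≈ 8 px apart in y: the
two spots share a scan region for many frames (the overlap machinery is
exercised continuously) but remain distinct candidates. Second, tracks are
advanced independently; two tracks may legitimately localize the same spot,
which is logged as a warning rather than forbidden.

## Sub-pixel localization

Two localizers operate on a `window_size` square around the integer candidate
(window clamped to lie inside the image):

* **Centroid**: the intensity-weighted mean of the background-subtracted
  window, with negative pixels clipped to zero (negative mass would push the
  centroid outside the signal). The reported intensity is the raw window sum
  minus background × (number of window pixels).
* **2D Gaussian** `I(x, y) = A exp(-(x-x_c)²/2w_x² - (y-y_c)²/2w_y²)`, fitted
  by log-linearized weighted least squares: `ln I` is a quadratic in x and y,
  and weighting each pixel by its squared intensity counteracts the noise
  amplification of the log transform at dim pixels. Pixels at or below
  background are excluded (their log is undefined). The fit is exact on
  noiseless Gaussian data — the round-trip against the simulator recovers all
  five parameters to 1e-6 — and costs one 5-parameter linear solve. A fit
  whose quadratic opens upward or whose centre leaves the window is declared
  unconverged and the engine falls back to the centroid. The reported spot
  intensity is the Gaussian integral `2πA·w_x·w_y`.

The background fed to both is the median of the scan-region pixels outside
the localization window. The per-point SNR column uses
`(μ_sig − μ_bg)/σ_bg` with signal = the localization window and background =
the scan region minus the window; here σ is the plain standard deviation,
matching the definition the SNR is quoted in.

## Trajectory analysis

The time-averaged MSD of an N-frame track is

ρ(nΔt) = Σᵢ [(x₍ᵢ₊ₙ₎ − xᵢ)² + (y₍ᵢ₊ₙ₎ − yᵢ)²] / (number of valid pairs),

in µm² after scaling by `pixel_size`. Pairs with a gap endpoint are dropped
from numerator and denominator; the error bars still use the full N (a
documented approximation — for lightly gapped tracks the correction is
far below the error bar itself). Each lag carries the closed-form relative
standard deviation of the TA-MSD estimator for Brownian motion (two branches,
n ≤ N/2 and n > N/2; exactly 1 at the single-pair lag n = N−1). Across 500
simulated Brownian tracks the empirical scatter of ρₙ follows this curve
within 7% for n ≤ N/4 — comfortably inside the 15% consistency bound we
test.

The diffusion coefficient comes from ordinary least squares of ρ(τ) = 4Dτ + b
over lags 1–4 by default: short lags keep the strongly correlated large-lag
points out of the fit, and the free intercept b absorbs static localization
noise. The anomalous exponent α is the slope of log ρ vs log τ over the same
lags (α = 1 Brownian, < 1 sub-diffusive, 2 ballistic). Negative fitted slopes
are reported and flagged rather than clamped.

## The synthetic-data generator

`simulate_movie()` emulates the data regime the tracker is designed for:
Gaussian spots (default width 1.5 px) of amplitude 100 on a background of
100 counts, additive Gaussian camera noise, 10 fps sampling, 0.1 µm pixels in
the test fixtures. Motion models: stationary, Brownian (per-axis step
variance 2DΔt), directed (the fixtures use 1.3 µm/s, the transport speed
regime of dendritic mRNA), and switching schedules. Blinking removes the spot
entirely for listed frames, emulating excursions out of the focal plane.
`calibrate_noise_for_snr()` inverts the SNR definition so movies can be
generated *at* a target SNR: σ = (expected window-mean excess of the spot)
/ SNR. Monte-Carlo round trips confirm measured SNR within 10% of target.

What the generator does **not** model — Poisson shot noise, EMCCD gain,
photobleaching decay, 3D defocus, structured cellular background — bounds
what passing tests prove: they validate the algorithmic contract (detection,
policy dispatch, localization accuracy, MSD statistics) under the noise model
whose σ_background is the only statistic the SNR definition uses, not
performance on any particular camera. Additive Gaussian noise was chosen
deliberately: it makes the SNR calibration exact and the localization-error
benchmarks interpretable.

## Numerical and convention choices

* Coordinates are 0-based; x = column, y = row; pixel centres at integer
  coordinates; region bounds inclusive. Stated once and used everywhere —
  half-pixel conventions are the classic source of drift in trackers.
* Rounding of sub-pixel centres uses round-half-up, making region placement
  deterministic and platform-independent.
* Window-mean ties are broken toward the candidate nearest the previous
  position, then row-major — determinism again.
* The scan region is re-centred on the *sub-pixel* localized position, not
  the integer window centre (marginally tighter regions; either reading is
  defensible).
* A `stopped` point records the last known position with `NaN` intensity;
  only `gap` points have all of x, y, intensity missing.
* Intensities are written to TIFF as 16-bit integers (the native range of
  scientific cameras); floating-point TIFFs are supported on input.

## Problem sizes

The shipped validation uses movies of 64×96 px and 25–50 frames, 100–500
simulated trajectories of 100–200 frames for the statistical checks, and 20
seeded replicates of the two-particle crossing. These sizes give the
stochastic checks margins of 2–3× over their tolerances (e.g. the MSD
consistency bound) while the whole suite runs in well under a minute.

## Limitations

* No inter-track exclusion or global assignment: this is a per-particle
  tracker by design; heavily crowded fields are out of scope.
* Identities through a genuinely merged blob are undefined (see above).
* The Qian error bars assume Brownian statistics; for directed or strongly
  sub-diffusive tracks they are indicative only.
* Motion-state classification (e.g. Bayesian MSD model selection) is left to
  downstream tools; the package reports D and α per track and stops there.
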