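---
title: "Counting microtubules in dense neuronal arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting microtubules in dense neuronal arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The problem

Dendrites of mammalian neurons carry dense arrays of microtubules whose
biochemical state — acetylated (long-lived, stable) versus tyrosinated
(freshly polymerized, dynamic) — organizes intracellular transport.
Super-resolution stacks of three immunofluorescence channels (total
α-tubulin, tyrosinated, acetylated) show this array but are too dense for
filament-by-filament tracing. `mtquant` converts such stacks into absolute
counts and spatial maps through intensity calibration: if we know the
integrated fluorescence contributed by *one* microtubule in each channel,
total intensities become counts.

## Single-filament calibration

**Model.** In a sparse region, per-segment background-corrected mean
intensities `I_segm` are measured with a dual-width band around each
detected filament: a 6-pixel band (`I_mid` over area `S_mid`) and a
13-pixel band, giving the local background
`I_BG = (I_wide − I_mid)/(S_wide − S_mid)` and
`I_segm = I_mid/S_mid − I_BG`. The histogram of `I_segm` over many
segments is fitted with

$$\rho(I) = a_1 e^{-(I - I_{Tot})^2 / 2\sigma^2}
          + a_2 e^{-(I - 2 I_{Tot})^2 / 4\sigma^2},$$

the second component being the exact self-convolution of the first
(mean $2I_{Tot}$, variance $2\sigma^2$): unresolvable two-filament
bundles. Segments with total-channel intensity strictly below
$I_{Tot}+\sigma$ are retained as singles.

Numerical notes:

* **Band semantics.** A pixel belongs to the width-*w* band iff its center
  projects onto a polyline segment within range and lies within *w*/2
  perpendicular — a stroked line *without end caps*, as ImageJ line ROIs
  behave. With rounded caps, `S_mid` exceeds `L·w` by `π(w/2)²` and the
  segment and dendrite normalizations stop being commensurate (a
  one-filament dendrite would count as ~1.09 filaments).
* **Binning.** Freedman–Diaconis bin widths, with the binned range extended
  to `2.4 × median` so that empty bins constrain $a_2$ when no doublets
  exist; otherwise the second component's amplitude is unidentifiable
  whenever its center lies beyond the data range.
* **Optimization.** Bounded nonlinear least squares (`nls`, port). Port's
  "false convergence" at an active bound ($a_2 = 0$ is common and
  legitimate) is accepted when the parameters are finite and positive;
  `optim` (L-BFGS-B) on the same objective is the fallback. Degenerate
  inputs (zero spread) are rejected.
* **Initial values.** $I_{Tot}$ from the histogram mode, $\sigma$ from half
  the interquartile range, $a_2$ from the data mass above $1.5 I_{Tot}$.

## Crosstalk and unmixing

Modification channels are not exclusive: stable microtubules carry a
residual tyrosination (mean normalized level α) and dynamic ones a
residual acetylation (β). With single-microtubule channel intensities
`I_Tyr`, `I_Ac`, dendrite intensities mix linearly:

$$I^{dend}_{Tyr} = (n_{Tyr} + \alpha\, n_{Ac})\, I_{Tyr}, \qquad
  I^{dend}_{Ac} = (\beta\, n_{Tyr} + n_{Ac})\, I_{Ac}.$$

Defining $\theta = I^{dend}/I_{single}$, the inverse is closed-form:
$n_{Tyr} = (\theta_{Tyr} - \alpha \theta_{Ac})/(1 - \alpha\beta)$,
$n_{Ac} = \theta_{Ac} - \beta n_{Tyr}$, with an explicit error when
$|1-\alpha\beta| < 10^{-6}$ (the two channels carry no independent
information). Negative unmixed counts are *reported with a flag, never
clamped* — clamping would bias population statistics.

α and β are estimated from singles: α is the mean tyr-channel intensity of
ac-detected singles divided by `I_Tyr`; β symmetrically. Both are ratios
and therefore invariant to any per-channel intensity rescaling.

## Dendrite counting

A straight 2–3 µm line of width `w_dendrite` (covering the dendrite's
thickness) is integrated on sum projections; a band widened by 10 px gives
the background. The normalization

$$I_{dend} = \frac{I_{mid} - I_{BG} S_{mid}}{L_{dend}\, w_{microtubule}}$$

(with `w_microtubule` the same 6-px width used in calibration) makes
$n_{Tot} = I^{dend}_{Tot} / I_{Tot}$ a count. The printed form of this
normalization in the source material is garbled; this reading is the one
under which the one-filament dendrite yields exactly one count, and the
package asserts that property in its tests. Calibration is per cell by
design; sharing a calibration across cells is possible but explicit.

Cross-section areas come from the boundary contour of a YZ reslice
(below), converted through the pixel size and expansion factor.

## Radial distribution machinery

Each straightened dendrite is resliced into isotropic YZ cross-sections
(z linearly resampled to the in-plane pixel size). Per slice:

1. **Bounding rectangle.** The maximal rectangle centered on the intensity
   center of mass is downsized per side by scanning the min–max-normalized
   edge-intensity derivative from the outside inward until it exceeds
   `I_thr` (default 0.3; the reference procedure chooses 0.2–0.4 by eye
   and gives no automatic rule, so the mid-range is the default and the
   parameter is exposed).
2. **Tracking.** Subsequent slices record candidate boundaries at all
   thresholds {0.1, …, 0.5}, scanning both directions, and keep the
   candidate closest to the previous slice's boundary (ties toward the
   larger rectangle). This resists axon cross-sections hugging the
   dendrite. A side with no candidate inherits and is flagged.
3. **Contour.** Four rectangle midpoints plus four diagonal points (where
   wide-band diagonal profiles first reach 0.175 of max per half) anchor a
   periodic cubic spline. For clean, low-background data the convex hull
   of local maxima is the faster alternative.
4. **Erosion profile.** The contour interior is eroded in 1-px steps via
   its Euclidean distance map; ring means
   $MI_k = (IC_{k-1} - IC_k)/(S_{k-1} - S_k)$ are indexed by the
   equivalent-circle radius $R_k = \sqrt{S_k/\pi}$ (normalized to the
   outermost). Negative ring means (pure noise) are clipped to zero and
   flagged. The density ρ(R) is `MI(R)` normalized to unit area, with the
   never-eroded central core included as a final term so that a flat field
   gives exactly ρ ≡ 1.

**Decomposition.** The total density is regressed on the tyr and ac
densities by unconstrained least squares with a closed-form
normal-equation solution; no sum-to-one constraint is imposed, so the
fitted weight sum is a diagnostic. On exact mixtures the weights are
recovered to machine precision; collinear components raise an error.

## FlipExM counting

In flipped expansion-microscopy geometry the poor axial PSF lies along the
dendrite axis, so YZ slices resolve individual microtubule cross-sections
as round spots. The stage:

* **Detection** smooths each slice, thresholds at 5 robust SDs above the
  median, labels 8-connected components, and splits components containing
  several intensity maxima — but only when the valley between two maxima
  drops below half the dimmer peak; a merged pair at ~1.5 PSF-FWHM
  separation stays one elongated spot for the roundness filter to reject.
  Width/height are bounding extents of the above-half-maximum core (the
  reference does not state its width definition; box extents at half
  maximum are used and documented here). Spot intensities are integrated
  over the core in all three channels, background-corrected by the median
  of a surrounding annulus.
* **Filters.** Roundness θ = w·h/max(w,h)² ≥ 0.8, then an MLE-normal area
  window [max(Q₁, S̄−σ), S̄+σ] computed on the roundness survivors per
  channel. All-equal areas degenerate to a single-point window with
  everything kept.
* **Calibration** refits the two-Gaussian model per channel on filtered
  spot intensities. Because per-microtubule crosstalk levels are broad and
  long-tailed, a channel's detections include crosstalk-level spots; a
  bright-reference selection (spots ≥ 0.75 of the median of the top third
  of detections, the approximate geometric midpoint between a worst-case
  crosstalk level ~0.6 and the single level) keeps them out of the
  calibration and out of the "detected-in-channel" crosstalk sets.
* **Crosstalk** is estimated three ways — pooled mean, a mean trimmed at
  mean+SD, and the dominant-peak position of a free two-Gaussian fit
  (falling back, flagged, to the trimmed mean) — because the level
  distributions have long right tails: the pooled mean is largest and the
  peak estimate smallest, and reporting all three exposes that spread.
* **Counting** sums *all* detected spot intensities per slice and channel
  (crosstalk-level spots must contribute: the forward model's α·n_Ac term
  is exactly that light), divides by the single cross-section intensity,
  unmixes per slice, and averages over slices per dendrite.

## The synthetic generator: what it emulates, what it does not

`simulate_scene()` produces the three statistical structures the analysis
assumes:

* **Soma sheet:** straight filaments (1.5–3 µm) in a thin axial sheet,
  placed sequentially with a 0.25 µm minimum separation (the sub-nuclear
  region is chosen in practice *because* it is sparse); a configurable
  fraction are two-filament bundles rendered as parallel filaments 40 nm
  apart — unresolvable, hence doubly bright.
* **Dendrite:** axial microtubules in a cylinder. Total packing is
  *uniform* over the cross-section (as electron microscopy shows);
  `radial_bias` ∈ [0, 1] biases the *subtype assignment* by noisy radial
  rank — 0 random, 1 perfectly segregated (stable core, dynamic shell).
  Biasing positions instead of identities would make the total channel
  center-peaked, which real dendrites are not, and which breaks the
  boundary-contour assumptions.
* **FlipExM dendrite:** the same with a 0.12 µm minimum cross-section
  separation (so single cross-sections are resolvable), flipped PSF by
  default, and an optional `circumferential` arrangement (equally spaced
  on the shell) for the PSF-orientation benchmark.

Channel model: every filament emits 1 in total; stable filaments emit 1 in
ac and `true_alpha × L` in tyr, dynamic 1 in tyr and `true_beta × L` in
ac, where `L` is a per-filament lognormal level (sdlog 0.35, mean 1):
per-microtubule modification levels are right-skewed and long-tailed in
real data, and a fixed two-level emission would create an artificial
second histogram peak in the crosstalk channel that captures the
calibration fit — an artifact of over-idealization, not of the method.
Independent per-channel multiplicative staining noise (CV 0.15) is
applied on top. Geometry is generated in biological µm and scaled by the
expansion factor before rendering; centerlines are splatted trilinearly at
quarter-voxel arc steps, smoothed by an isotropic Gaussian of
0.3 × lateral PSF, convolved with the anisotropic PSF (long axis along z,
or along the dendrite axis when flipped), then background and Poisson
(optionally Gaussian read) noise are added. Everything before noise is
recorded as ground truth.

Defaults represent STED acquisition: 30 nm pixels, 150 nm z-steps,
lateral PSF σ 30 nm, 20 000 photons/µm, background 5 photons. The
acceptance scenes use an axial σ of 0.1 µm ("3D STED", approximately
isotropic): with the 2D-STED axial σ of 0.25 µm, axial blur alone inflates
cross-section areas of ~2 µm dendrites by ~20% — the very limitation that
motivated 3D STED and FlipExM in the first place, and a caveat to keep in
mind when applying the area pipeline to 2D-STED data.

What the generator does **not** emulate: real (non-Gaussian, aberrated)
PSFs, depletion-beam physics, gel distortion, photobleaching, filament
curvature inside dendrites, antibody labeling stochasticity beyond the
multiplicative level noise, and deconvolution artifacts. A green test
therefore establishes that the *estimators are correct on data satisfying
their stated assumptions* — not that those assumptions hold for any
particular microscope.

Numerical detail worth knowing: the edge-intensity curves of the
rectangle scan are smoothed (3-px moving average) and normalized against a
robust (95th-percentile) maximum before thresholding — on discrete
microtubule arrays the raw derivative is spiky, and a single bright
filament would otherwise set the normalization and drag every crossing
into the interior. On clean solid objects this costs at most ~2 px of
boundary accuracy.

## Known limitations

* The internal ridge detector is deliberately simple (threshold +
  component tracing); crossing filaments merge. Detection is pluggable:
  externally traced ImageJ ROIs are first-class inputs
  (`segments_from_rois()`), which is also how the reference workflow
  operated.
* Detection "specificity" in a channel (singles of that subtype, not
  crosstalk-level filaments) is intensity-based and therefore degrades as
  true crosstalk levels approach 1; α, β estimates inherit an upward bias
  of a few hundredths at β ≈ 0.6.
* Cross-section areas are boundary-threshold dependent; at 2D-STED axial
  resolution they are biased high, and for very sparse arrays the
  intensity support is genuinely smaller than the geometric cylinder.
* Counting assumes the calibration and target share acquisition settings
  (same cell, same imaging mode) — as the per-cell design mandates.
* The innermost erosion rings of a radial profile average very few pixels
  around the contour's deepest point; their ring means are noisy, and
  single-dendrite densities can show a spurious core bump (amplified in
  the tyrosinated channel by the genuine α-crosstalk of core stable
  microtubules). Population averages, as used for the reference radial
  distributions, wash this out; peak-position statements should exclude
  R below ~0.15.
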