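# mtquant

Quantitative mapping of dense microtubule arrays in neurons from
multi-channel super-resolution fluorescence stacks.

Neuronal dendrites pack tens of microtubules per square micrometre — far
too dense to count by eye even in super-resolution images. `mtquant`
implements a set of intensity-calibration and geometry methods that turn
three-channel stacks (total α-tubulin, tyrosinated tubulin = dynamic
microtubules, acetylated tubulin = stable microtubules) into absolute
microtubule numbers and spatial maps:

1. **Single-filament intensity calibration.** In a sparse region (the
   sheet of filaments under the nucleus, or microtubule cross-sections in
   FlipExM slices), individual filaments are detected and their
   background-corrected intensities histogrammed. The histogram is fitted
   with a two-Gaussian model

   ρ(I) = a₁·exp(−(I−I_Tot)²/(2σ²)) + a₂·exp(−(I−2·I_Tot)²/(4σ²)),

   whose first component is the single-microtubule intensity distribution
   and whose second is its self-convolution (two-filament bundles). The
   fitted I_Tot converts integrated intensity into counts; segments below
   I_Tot+σ are "singles" used for everything downstream.

2. **Crosstalk unmixing.** Acetylation and tyrosination are not mutually
   exclusive: singles detected in the acetylated channel still carry a
   mean normalized tyrosination α, and tyr-detected singles a mean
   acetylation β. Dendrite channel intensities therefore mix as
   θ_Tyr = n_Tyr + α·n_Ac and θ_Ac = β·n_Tyr + n_Ac, inverted in closed
   form: n_Tyr = (θ_Tyr − α·θ_Ac)/(1 − αβ), n_Ac = θ_Ac − β·n_Tyr, with
   n_Other = n_Tot − n_Tyr − n_Ac.

3. **Radial density profiles.** Straightened dendrites are resliced into
   YZ cross-sections; the dendrite outline is found by a rectangle
   edge-scan plus an 8-anchor periodic spline (or the convex hull of local
   maxima), and iterative 1-px contour erosion yields the radial density
   ρ(R) of each channel versus the normalized equivalent radius
   R = √(S/π). The total density decomposes in closed form into
   w_Tyr·ρ_Tyr + w_Ac·ρ_Ac; empirically w_Tyr + w_Ac ≈ 1.

4. **FlipExM cross-section counting.** In expanded gels flipped 90°, the
   poor axial PSF lies along the dendrite axis and each YZ slice shows
   microtubule cross-sections as round spots. Spots are filtered by
   roundness θ = w·h/max(w,h)² ≥ 0.8 and by an MLE-normal area window
   [max(Q₁, S̄−σ), S̄+σ], calibrated with the same two-Gaussian model, and
   counted per slice via the unmixing system.

5. **Synthetic microscopy generator.** Every stage is testable without
   data downloads: `simulate_scene()` renders ground-truth-labelled soma
   sheets (with two-filament bundles), dendrites with core/shell subtype
   segregation, and FlipExM dendrites, with channel crosstalk, anisotropic
   Gaussian PSF in regular or flipped orientation, and Poisson noise.

## Worked example

```r
library(mtquant)

# calibrate on a synthetic sub-nuclear soma sheet
soma <- simulate_scene(scene_spec(
  "soma_sheet", n_microtubules = 200, bundle_fraction = 0.2,
  fraction_acetylated = 0.45, fraction_tyrosinated = 0.45,
  fraction_other = 0.10, psf_sigma_axial = 0.1,
  true_alpha = 0.53, true_beta = 0.45, seed = 101))
cal <- calibrate_soma(soma$stack)
cal
#> soma_calibration
#> single_intensity_fit: I_Tot = 100.3, sigma_Tot = 13.98 (n = 180)
#>   singles threshold I_Tot + sigma = 114.3; a2/a1 = 0.478
#> crosstalk: alpha = 0.471, beta = 0.430 (I_Tyr = 108.4, I_Ac = 109.8; n = 34/30)
#>   180 segments measured, 85 singles kept

# count a synthetic dendrite (3 um^2, true density 53 MT/um^2)
dend <- simulate_scene(scene_spec(
  "dendrite", n_microtubules = 159, dendrite_diameter = 1.954,
  dendrite_length = 4, fraction_acetylated = 0.72,
  fraction_tyrosinated = 0.26, fraction_other = 0.02,
  psf_sigma_axial = 0.1, true_alpha = 0.53, true_beta = 0.45,
  radial_bias = 0.8, seed = 202))
count_dendrite_sted(dend$stack, cal)
#> dendrite_count (area 2.67 um^2, band 72 px):
#> microtubule_counts: n_tot = 158.7 (tyr 46.3, ac 101.4, other 11.0)
#>   fractions: tyr 29.2%, ac 63.9%, other 6.9%; density 59.4 MT/um^2
```

The truth for this scene is 159 microtubules over 3.0 µm² (53 MT/µm²)
split 26/72/2% — the pipeline recovers the density within ~12% and every
fraction within 10 percentage points, mirroring the method's behaviour on
real data (reported dendritic densities of 68 and 53 MT/µm² for the
soma-calibrated and dendrite-intrinsic routes).

Radial analysis and FlipExM counting run the same way from a reslice:

```r
resl <- straighten_and_reslice(dend$stack,
                               polyline_roi(rbind(c(30, 49), c(103, 49))),
                               half_width = 47)
ra <- analyze_radial(resl)
ra$decomposition
#> decomposition: w_tyr = 0.556, w_ac = 0.436 (sum 0.992), MSE = 0.00253
```

## Command line

```sh
Rscript -e 'mtquant::mtq_cli()' run --config config.json
```

with verbs `simulate`, `filaments`, `count`, `radial`, `flipexm`,
`profile`, `run`; one JSON config drives a whole run (see
`?read_run_config`).
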