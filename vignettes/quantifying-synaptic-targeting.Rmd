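---
title: "Quantifying presynaptic channel localization with synquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic channel localization with synquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
library(dplyr)
```

## The measurement problem

Whether a voltage-gated calcium channel supports transmitter release depends
on whether it sits at the presynaptic active zone, tens of nanometers from
the postsynaptic density, or merely somewhere on the axon. Resolving that
difference requires super-resolution (STED) imaging and a quantification
scheme that reduces each synapse to a one-dimensional intensity profile
along the trans-synaptic axis. synquant implements that scheme:

1. **Side-view selection.** Only synapses whose postsynaptic density
   (PSD-95) appears as an elongated bar at the edge of a synapsin-labeled
   vesicle cloud define a meaningful trans-synaptic axis. The package
   supports annotation files (the workflow used on real data, where
   selection is manual and blind) and an automated surrogate
   (`detect_side_view_synapses()`) based on Otsu segmentation and
   second-moment shape analysis, used for testing against ground truth.
2. **Perpendicular line profiles.** At each accepted synapse a rectangular
   ROI, ~1000 nm long and 200 nm wide, is drawn perpendicular to and across
   the center of the PSD-95 bar (`extract_profile()`). The profile is
   sampled by bilinear interpolation with a step equal to the pixel size
   (14.194 nm in the reference regime) and averaged across the 200 nm
   width. Positions are signed so that the presynaptic side — the side of
   the PSD axis holding more synapsin mass — is negative.
3. **Alignment and peak extraction.** The PSD-95 profile is smoothed with a
   5-pixel rolling average; its maximum defines position zero
   (`align_profiles()`). The channel of interest is never smoothed. Peak
   level and position are the maximum of each aligned profile within a
   200 nm window around zero (`peak_in_window()`). Per-synapse peak values
   are the unit of analysis for the statistics.
4. **Confocal ROI quantification.** For expression-level comparisons, the
   synapsin channel is Otsu-thresholded; connected components of at least
   0.05 µm² (249 pixels at 14.194 nm pitch) become ROIs; per-image averages
   of per-ROI channel intensity are the unit of analysis
   (`segment_channel()`, `label_components()`, `filter_min_area()`,
   `measure_rois()`, `image_summary()`).
5. **Somatic donuts.** Somatic expression is the mean channel intensity in
   a donut ROI: the soma outline (NeuN) minus the nucleus (EGFP), one value
   per cell (`build_donut_mask()`, `measure_soma()`).
6. **Statistics.** Nonparametric tests throughout: Kruskal–Wallis with
   Dunn's post hoc for single-factor multi-group comparisons, Friedman with
   Dunn's for repeated pharmacology stages, Wilcoxon matched-pairs
   signed-rank for paired designs, and a two-way repeated-measures ANOVA
   with Dunnett's comparisons for genotype × stage designs.

## The synthetic-data generator

Real two-color STED images of cultured neurons are not redistributable, so
the package ships a generator whose defaults emulate the acquisition regime
the analysis was designed for and whose every parameter is recorded as
ground truth.

- **Optics.** 58.14 × 58.14 µm² fields at 4096 × 4096 px (14.194 nm
  pixels); Gaussian PSFs of 60 nm FWHM (STED; channel of interest and
  PSD-95) and 250 nm (confocal; synapsin). Somatic fields default to
  92.65 µm / 1024 px / 90.2 nm pixels.
- **Structures.** The PSD is a 400 × 80 nm box, the channel band a
  400 × 60 nm box displaced along the trans-synaptic axis, the vesicle
  cloud an isotropic Gaussian (σ = 300 nm) centered 250 nm presynaptic to
  the PSD. Boxes have 10 nm Gaussian edge softness. These are the simplest
  shapes consistent with an elongated PSD at the edge of a vesicle cloud;
  published EM and STED morphometry of hippocampal synapses puts PSD long
  axes at 300–500 nm, which motivated the defaults.
- **Offsets.** In the `targeted` regime the channel offset is drawn from
  Normal(−50 nm, 15 nm) — on the presynaptic side, within tens of
  nanometers of the PSD-95 peak. `absent` sets the channel amplitude to 0;
  `reduced` scales it to 30%. No quantitative offset distribution for real
  channels is established; these defaults are declared stand-ins, exposed
  in the configuration, not claims about biology.
- **Rendering.** Convolution with the PSF is analytic (a box convolved with
  a Gaussian is a product of normal-CDF edge terms; a Gaussian cloud
  convolved with a Gaussian PSF is a Gaussian with summed variances), so
  the noiseless image is exact rather than FFT-approximated. Soma disks use
  the one-dimensional edge profile A·Φ((R − r)/σ), accurate because soma
  radii (8 µm) dwarf the PSF (σ ≈ 106 nm). Poisson noise draws counts at
  `photon_scale` × expectation per pixel; the noiseless render is exactly
  the expectation of the noisy one.
- **Seeding.** A single top-level seed; per-synapse and per-channel child
  seeds are derived by an affine splitting rule, so adding synapses to a
  scene never perturbs the ones already placed, and every render is
  bit-reproducible.

What the generator does *not* emulate: out-of-focus light and 3-D
structure, antibody labeling stochasticity, detector gating, photobleaching,
chromatic offsets between channels, and the morphological diversity of real
synapses. Passing tests on synthetic data therefore validate the
*measurement machinery* — geometry, alignment, calibration, statistics —
not the biological interpretability of any particular staining.

## Numerical choices and tie rules

- **Rolling average.** Centered, window 5 pixels; at the ends the window is
  truncated to the samples that exist (no padding), so
  `smooth_rolling_average(c(5, 0, 0, 0, 0), 5)[1]` is 5/3. Smoothing is
  applied to PSD-95 only; the channel of interest is analyzed raw.
- **Peak ties.** `locate_psd_peak()` breaks ties toward the smallest
  position; `peak_in_window()` toward the position nearest zero, then the
  negative (presynaptic) side. Both rules are deterministic and
  order-independent.
- **Otsu.** 256-bin histogram spanning [min, max], objective computed from
  exact per-bin sums, pixels strictly above the threshold are foreground,
  ties break toward the smallest threshold. A constant image is a
  degenerate-image error. For the *detection surrogate only*, Otsu is
  iterated on the foreground until it occupies at most 5% of the field:
  sparse PSD bars occupy so few pixels that a single pass splits the
  background mode instead. ROI segmentation of the synapsin channel keeps
  the single pass, matching its use on densely innervated fields.
- **Connectivity.** 8-connected components by default ("contiguous" is
  ambiguous and the choice changes counts, so it is exposed); labels are
  assigned in column-major scan order. The area floor is boundary
  inclusive: exactly 0.05 µm² is retained.
- **Donuts.** Polygons rasterize by the pixel-center even-odd rule; the
  nucleus is clipped to the soma, so donut + (soma ∩ nucleus) = soma holds
  exactly in pixels.
- **Profile boundary.** A rectangle that exits the image is a boundary
  error; the synapse is excluded with a warning, never padded.
- **Dunn's adjustment** defaults to the Bonferroni-type rule min(1, m·p)
  because the upstream software's correction is not documented; the rule is
  an argument (`adjust`) so alternates can be swapped. Dunnett comparisons
  use the deterministic `dunnettx` approximation rather than the
  quasi-Monte-Carlo exact method, keeping whole-pipeline outputs
  byte-reproducible.
- **Units of analysis** are enforced: a `unit` column with mixed values
  (synapses and images, say) in one test is an error, because pooling
  different units silently inflates n.

## Design decisions that were genuinely open

- **Width averaging.** Whether the 200 nm ROI width is averaged or
  maximized is not specified by the upstream description of the method;
  synquant averages (the convention of standard line-profile tools) and
  exposes the choice implicitly through `extract_profile()`'s contract.
- **Side-view criteria.** Manual selection quantifies no elongation cutoff.
  The automated surrogate defaults to elongation ≥ 2 (a 400 × 80 nm bar
  measures ≈ 4–5 after PSF widening; round face-view PSDs measure ≈ 1) and
  synapsin adjacency within 150 nm.
- **Coverage rule.** After alignment, grid positions covered by fewer than
  half the synapses are dropped from the mean profile; edge positions
  otherwise average over arbitrarily few synapses.
- **Blinding.** `run_experiment()` processes conditions under coded labels
  and restores true labels from the key only at the statistics stage,
  mirroring experimenter blinding.

## Problem sizes used in tests

Tests and the acceptance script run the pipeline at reduced field sizes —
512–2048 px per side rather than 4096 — with the pixel pitch, PSFs,
amplitudes and noise model unchanged. The quantities being validated
(per-synapse offsets, areas in µm², rank statistics) are local and do not
depend on the field extent, so smaller fields with proportionally fewer
synapses measure the same thing; 100 synapses per noise-regime check and
2000 replicates for the type-I-error calibration give the comparisons
adequate precision. Offset-recovery accuracy is limited by the sampling
grid: one 14.194 nm pixel noiselessly, and a median error of a few
nanometers under Poisson noise at the default photon scale, because
averaging across the 200 nm ROI width suppresses shot noise.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(
  conditions = list(
    control      = list(regime = "targeted"),
    cTKO         = list(regime = "absent"),
    rescue       = list(regime = "targeted"),
    nontargeted  = list(regime = "absent")),
  reference = "cTKO",
  optics = optics_spec(field_px = c(1024L, 1024L)),
  n_synapses = 14, mode = "truth", seed = 23)
run <- run_experiment(cfg)
run$omnibus      # Kruskal-Wallis across the four conditions
run$posthoc      # Dunn vs cTKO: rescue/control reject, nontargeted does not
run$figures$profiles
```

## Known limitations

- 2-D only: no z-stacks, no axial PSF, no optical sectioning model.
- The automated detector is a testing surrogate; on real, crowded images
  manual side-view selection (annotation mode) remains the intended path.
- No deconvolution, drift correction, or intensity normalization across
  biological repeats — the analysis assumes imaging settings are held
  constant within a repeat, as in the acquisition protocol it models.
- The Poisson model omits read noise and gain; for gated STED detectors
  this is mild, but absolute SNR claims should not be transferred to other
  hardware.
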