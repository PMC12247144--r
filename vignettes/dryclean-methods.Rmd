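---
title: "Cleaning dry EEG with ICA, jump zeroing and spatial harmonic filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning dry EEG with ICA, jump zeroing and spatial harmonic filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Dry-electrode EEG trades preparation time for robustness: without the gel
that mechanically damps the electrode–skin interface, recordings carry more
broadband sensor noise, more movement-related transients, and the usual
physiological interference (blinks, eye movements, muscle, heartbeat). This
package implements a cleaning pipeline built from three complementary
stages, together with the synthetic data and metrics needed to exercise it
end to end:

1. **FPA stage** — ICA-based removal of physiological artifacts;
2. **AP0** — zeroing of transient single-channel high-amplitude jump
   periods *before* any spatial filtering;
3. **SPHARA** — a spatial low-pass on the eigenbasis of the
   Laplace–Beltrami operator discretized over the triangulated sensor
   montage.

## The processing phases

**Phase A (preprocessing).** Zero-phase FIR band-pass 0.5–70 Hz plus a
48–52 Hz FIR band-stop, both Hamming windowed-sinc designs applied
forward–backward in the frequency domain (multiplication by the squared
magnitude response), so no group delay is introduced. The band-pass uses a
0.5 Hz transition at the low edge. Channels that are isoelectric
(|x| < 0.5 µV) or sustained high-amplitude (|x| > 100 µV) for more than 70%
of the samples are flagged and removed. The preprocessed signal is the
reference (`Ref`) every cleaning method is compared against.

**Phase B (cleaning).** Four chains are dispatched by
`run_method_chain()`: `fpa`, `sphara`, `fpa+sphara`, and
`fpa+ap0+sphara`. The AP0 step always sits between the ICA stage and the
spatial filter, because ICA is insensitive to rare single-channel jumps
while any spatial filter smears them across the montage.

**Phase C (preparation).** Common-average re-referencing, spherical-spline
restoration of the channels removed in phase A, and segmentation into 7 s
task epochs (labels L, R, T, F), with trials disturbed on more than 40% of
channels dropped.

**Phase D (evaluation).** Per-channel SD, and SNR/RMSD against `Ref`:

$$\mathrm{SNR} = 10\log_{10}\frac{\sum_i x_\mathrm{Ref}(i)^2}
{\sum_i x_\mathrm{m}(i)^2}, \qquad
\mathrm{RMSD} = \sqrt{\tfrac1M \sum_i \big(x_\mathrm{m}(i) -
x_\mathrm{Ref}(i)\big)^2}.$$

This SNR is a power-attenuation measure, not a conventional signal/noise
separation: the more artifact and noise power a method removes, the larger
the value. Metrics are computed on the continuous pre-phase-C signals
(epoch-level computation is available via the segmentation API), and
aggregated channels → recording → grand mean with equal weights.

## The SPHARA stage

The basis functions are solutions of the generalized eigenproblem
$S v = \lambda M v$ with the cotangent stiffness matrix $S$ and consistent
mass matrix $M$ of linear finite elements on the triangulated electrode
surface. The montage is triangulated by 2D Delaunay in an
azimuthal-equidistant projection about the cap apex — EEG caps are open
disks, and convex-hull triangulation would add spurious bottom faces.
Natural (Neumann) boundary conditions keep constants in the null space;
obtuse-triangle cotangents are kept signed (a clamping option exists for
pathological montages). Eigenpairs are mass-orthonormalized, sorted by
eigenvalue with a stable tie-break, and sign-fixed (largest-magnitude entry
positive). The natural spatial frequency of BF $k$ is $\sqrt{\lambda_k}$,
and the eigen-solve is a dense symmetric reduction via the Cholesky factor
of $M$ — at 64–256 channels an iterative solver would buy nothing.

Filtering applies the order-2 Butterworth gain
$g_k = \big(1 + (f_k/f_c)^{4}\big)^{-1/2}$ to each coefficient, identically
at every time sample, so temporal phase is untouched. The cutoff $f_c$ is
the natural frequency of the $K$-th BF, where $K$ is the smallest count of
lowest-frequency BFs carrying 95% of the recording's power. The coupling of
the power criterion to the Butterworth cutoff is the simplest composition
of the two rules; a hard-truncation mode is provided for sensitivity
checks. Retaining 100% power is treated as an infinite cutoff (unit gain
everywhere) so that the degenerate configuration is exactly the identity
rather than a filter with −3 dB at the top of the spectrum. The power
subset is computed per recording; a fixed cutoff can be passed explicitly
when a dataset-global choice is preferred.

## The AP0 stage

Jump periods are detected per channel with explicit amplitude rules:
every exceedance of ±150 µV seeds a period starting 200 ms before the first
crossing (extended earlier while the signal already sits outside ±80 µV)
and ending at the first sample from which the signal stays within ±80 µV
for 200 ms. Periods closer than the 0.5 s taper are merged so taper ramps
never overlap. Detected (or manually labeled) periods are set to exactly
0 µV with half-Hann ramps of 0.25 s on each side, the spatial filter runs
on the zeroed data, and the affected spans are finally restored by
spherical-spline interpolation from the other channels (a mesh-neighbour
mode exists; "surrounding channels" is ambiguous and all-channel splines
are the default).

Two details deserve honesty. First, re-applying the zeroing with the same
period list reproduces the zero core and all untouched samples exactly, but
compounds the multiplicative Hann ramps — smooth transitions and strict
idempotence over the ramps are mutually exclusive, and the smooth
transition is what the method requires. Second, the detector is this
package's automation of what was originally a manual labeling step; its
defaults are exactly the printed rules, and a label-file path offers full
fidelity to manual annotations.

## The ICA stage

The data are PCA-whitened and reduced to a fixed 50 dimensions (comparable
decompositions across recordings with differing bad-channel counts), then
unmixed with extended Infomax (`ica::icaimax`, sign-switching between sub-
and super-Gaussian densities; deterministic given the seed through a seeded
random orthogonal initial rotation). The published trained classifiers for
artifactual components are not reproducible from their description, so
classification is a documented heuristic with every threshold exposed in
`classifier_thresholds()`:

* **blink** — frontal-dominant topography, >60% spectral power below 5 Hz,
  positive skew > 1 and excess kurtosis > 3 (sparse one-sided transients);
* **eye movement** — frontal, laterally dipolar *and* bilaterally balanced
  topography with slow step-like time course (the balance requirement keeps
  single-channel artifacts from masquerading as EOG);
* **myogenic** — >45% power above 20 Hz, fast decorrelation (lag-1
  autocorrelation below 0.5 evaluated on a ~256 Hz time base; at the native
  1,024 Hz every band-limited source is lag-1 correlated), and a bursty
  short-time envelope (CV > 0.5) so stationary sensor noise is left for the
  spatial filter;
* **cardiac / pulse** — a quasi-periodic peak train with median inter-peak
  interval in 0.67–1.67 s, low interval dispersion, and peaks at ≥70% of
  the expected beats; spiky trains (excess kurtosis > 3) are `cardiac`,
  smoother ones `pulse`;
* everything else **neural**.

The PCA dimension equals the IC count (rank-50 whitening); whether the
original work retained additional PCA variance is unknowable from its
description, and the identity choice is the least surprising. On
rank-deficient input the component count is capped at the numerical rank
with a warning.

## The synthetic generator

`generate_recording()` emits 64-channel, 1,024 Hz recordings plus an exact
additive ground truth. Design choices, made once:

* **Background** — the lowest-quartile SPHARA BFs of the montage mesh
  (constant excluded), each modulated by AR(2) low-pass noise (double pole
  at 0.995) with 1/k weighting, plus an amplitude-modulated posterior 10 Hz
  alpha oscillation projected into the same low-frequency span. The
  background is therefore spatially smooth *by construction* — exactly the
  "spatially correlated signal" half of the separation SPHARA assumes.
* **Artifacts** — frontal sin² blink pulses (~130 µV, 0.2–0.35 s); bilateral
  dipolar saccade steps (40–90 µV, 40 ms ramps); 20–100 Hz band-limited
  EMG bursts on low-lying rim channels; a QRS-like biphasic spike train at
  the configured heart rate (10–20 µV, 3% RR jitter) with a broad
  left-lateralized field.
* **Sensor noise** — i.i.d. Gaussian, default SD 8 µV. The share was chosen
  so uncorrelated noise is roughly a quarter of total power, mirroring the
  substantial power share that purely spatial filtering strips from dry
  recordings; gel-EEG values (~2–3 µV) would make the SPHARA stage nearly
  idle.
* **Jumps** — single-channel steps of 200–800 µV with exponential return
  (τ = 0.3 s) and a small negative rebound, durations 0.3–1.5 s, Poisson
  onsets targeting 1.3% of channel-time (the share reported for labeled
  jump periods in dry recordings of this kind, ±0.9% across datasets).
* **Reproducibility** — one master seed derives per-component substreams;
  the caller's RNG state is preserved.

What the generator does *not* emulate: volume conduction from realistic
cortical sources, task-locked motor activity, electrode drift, or
correlated (e.g., cable-borne) noise. Passing tests therefore demonstrate
that each stage does what it claims under the statistical structure it
assumes — not that cleaning performance on any particular hardware will
match the synthetic numbers.

## Benchmark conditions and what they show

The shipped benchmark runs 11 independent recordings of 60 s each (64
channels, 1,024 Hz, all artifact classes). Sixty seconds keeps the full
ICA-based chains comfortable on a single CPU while leaving ~50–100 jump
events per recording; the direction-level conclusions are insensitive to
duration. On this benchmark the grand averages order exactly as the method
design predicts: SD falls monotonically along
Ref → FPA → FPA+SPHARA → FPA+AP0+SPHARA, while SNR and RMSD rise along
FPA → FPA+SPHARA → FPA+AP0+SPHARA; the AP0 step produces by far the
largest single improvement because zeroed jumps no longer inflate the 95%
power cutoff, which in turn lets the spatial filter actually filter.

One caveat the benchmark makes visible: with the default jump amplitudes,
jump energy dominates the spatial power spectrum, so the data-driven cutoff
of the *non*-AP0 chains is high and their spatial filtering weak. For
mid-amplitude jumps whose neighbours' error is then noise-dominated, the
per-jump anti-smearing comparison between the with- and without-AP0
branches is occasionally won by the weaker filter (~10–15% of jumps). On
single-jump fixtures — where the cutoff is driven by the smooth background —
zeroing strictly reduces neighbour-channel error in every seeded instance.

## Numerical choices

* Half-open, 0-based sample intervals everywhere; microvolts everywhere.
* FIR edge handling: mirror padding of one kernel length; degenerate
  rank-deficient ICA inputs are capped at the numerical rank; spline
  interpolation uses Perrin-style m = 4 smoothing splines with 50 Legendre
  terms and a 1e−8 ridge (constants still reproduced exactly through the
  constraint row).
* Eigenvalue ties are left in solver order (stable sort) before
  sign-fixing; this makes repeated basis computations bit-identical.
* EDF export quantizes to 16 bits per channel range; BrainVision export is
  float32 and lossless for round trips.

## Limitations

The component classifier is a surrogate tuned to the generator's artifact
families; on real recordings its thresholds should be audited per dataset.
The 95%-power criterion is computed per recording, which couples the filter
strength to artifact load — an explicit `cutoff_frequency` decouples it.
The trial-rejection and bad-channel rules are explicit-threshold
realizations of what is usually visual inspection.
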