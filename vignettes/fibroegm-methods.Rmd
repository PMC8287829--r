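---
title: "Modeling fibrotic atrial substrate and its electrogram signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fibrotic atrial substrate and its electrogram signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fibroegm)
```

## The problem

Bipolar voltage mapping labels atrial tissue "fibrotic" when the local
peak-to-peak electrogram amplitude falls below a single cutoff (0.5 mV
during sinus rhythm). That rule conflates amplitude with substrate: wavefront
direction, catheter contact, and conduction velocity all move amplitude
without any fibrosis, and conversely fibrotic tissue can stay above the
cutoff. `fibroegm` builds a fully synthetic, ground-truth-labeled counterpart
of that clinical situation: it simulates atrial tissue patches with
parameterized interstitial fibrosis, synthesizes the catheter electrograms a
mapping system would record, corrupts them with a fitted autoregressive model
of catheter-lab noise, extracts seven morphology and complexity features, and
trains decision-tree classifiers that recover the presence, density, and
transmural depth of fibrosis from single bipolar signals.

## Tissue and propagation model

Tissue patches are regular voxel grids (element edge 1/3 mm in the
desk-scale study configuration, 0.2 mm available for the full-scale patch)
with fibres along +x, the endocardium at z = 0, and the epicardium at
z = wall thickness. Excitation propagates by an operator-split explicit
monodomain reaction-diffusion model: the diffusivity per axis is the
harmonic mean of intra- and extracellular conductivity (equal-anisotropy
reduction) scaled into mm^2/ms by the surface-to-volume ratio
(1400 cm^-1) and membrane capacitance (1 uF/cm^2). Baseline conductivities
(0.174/0.0347 S/m intracellular, 0.625/0.236 S/m extracellular) give a
diffusivity anisotropy near 2.3:1, i.e. a conduction-velocity ratio of about
1.5:1, typical of atrial working myocardium.

The ionic kinetics are a reduced two-variable model (fast inward current
gated by a single recovery variable, slow linear outward current) with time
constants tuned to an atrial action-potential duration of about 205 ms for
the control variant and 145 ms for the AF-remodeled variant. The model is a
contract: the resting state is a fixed point, a suprathreshold 2 ms stimulus
elicits a finite action potential, and any replacement honouring that
contract can be dropped in. The classifier consumes wavefront-level
morphology, which this model reproduces; single-channel kinetics, restitution
details, and drug effects are outside its scope.

Absolute conduction velocity is never taken from the literature conductivity
values directly: the dimensionless monodomain `scale` is calibrated in a
1-D strand at the same element spacing until the measured plane-wave CV hits
the target (30 or 40 cm/s) within 1%, so the discretization error at the
working resolution is absorbed into the calibration. A square-root
CV-diffusivity law makes the iteration converge in a few strand runs.
The pacing amplitude is twice the *tissue* diastolic threshold, bisected in
a loaded strand, because the electrotonic drain of coupled tissue makes the
single-cell threshold insufficient at fine spacings.

Numerics: explicit Euler with `dt = 0.125 ms` at 1/3 mm spacing, inside
the stability bound (about 0.19 ms at the largest fibrotic conductivities);
the kernel flushes membrane values below 1e-12 to zero, since the
exponential repolarization tail otherwise drifts into denormal floating
point arithmetic and dominates run time. A runtime guard aborts with a
diagnostic if the state leaves physiological bounds.

## Fibrosis model

Interstitial fibrosis is textured: collagen fibres (mean length 0.6 mm,
SD 0.2 mm) are placed at uniformly random positions along the local fibre
direction inside a circular region, from the endocardium down to the
requested transmural depth (0.5, 1, or 2 mm), until the collagen volume
fraction is within 0.02 of the target density (10, 20, 40, 60%). Collagen
elements get an extracellular conductivity of 1e-6 S/m and effectively no
intracellular pathway, so they act as diffusion barriers. Remaining myocytes
inside the fibrotic volume model gap-junction remodeling: longitudinal
intracellular conductivity reduced to 47%, transverse increased 2.5-fold.
Identical seeds reproduce identical textures.

The density and transmurality series vary one characteristic at a time:
densities are simulated at full transmurality and transmuralities at the
highest density. Crossing the two factors would conflate total fibrotic
burden (density x depth) and make, say, a shallow dense patch
indistinguishable from a deep sparse one — the one-at-a-time design keeps
each classification task well posed, and `task_subset()` restricts each
task to its series.

## Electrogram synthesis

Extracellular unipolar potentials come from the infinite-homogeneous-medium
Green's function applied to the intracellular source density
`-div(sigma_i grad Vm)`: each element contributes its source divided by
`4 pi sigma_b r`, with the distance averaged over points sampled on the
electrode footprint (radius 1 mm for the study catheter, approximating the
sensing area of the cylindrical electrodes of a real HD grid). This replaces
a full bidomain solve with bath and metallic electrode boundary conditions;
it preserves the source physics and the relative amplitude effects that
carry the substrate information, at a small fraction of the cost. The
absolute mV scale is fixed once per study by the constant `k_amp`,
calibrated so the mean control bipolar peak-to-peak amplitude across all
control conditions equals 2.25 mV, and then frozen across all conditions.

The study catheter is a 4 x 4 HD grid with 3 mm spacing and 12 along-spline
bipoles, rotated 30 degrees in-plane: an axis-aligned grid cancels a plane
wave travelling along a spline direction exactly in every bipole, a
degeneracy a real catheter never exhibits. A 20-pole circular (lasso-style)
layout with alternating 2/6 mm arc spacing is also provided. Electrograms
are sampled at 2 kHz for 2.5 s; four pacing pulses at a 600 ms cycle length
give about four activations per trace.

## Noise model

Catheter-lab noise is modeled as a global autoregressive process. The
pipeline fits it the way a clinical noise model would be fitted: activity
segments are detected and blanked (with a 10 ms guard) from pseudo-clinical
traces — control simulations plus a fixed reference colored-noise process —
and each of the 13 retained noise segments is fitted at candidate orders
1..10 (least squares), with per-segment orders chosen by BIC. The global
order minimizes the AIC summed across segments; all segments are re-fitted
at that order and coefficients and innovation variance averaged. If the
average is non-stationary, its characteristic roots are radially shrunk to
0.99 and the model flagged. Injection scales the generated noise so the
ratio of active-window signal power to noise power matches the requested
SNR (20 dB for the study dataset; 15-25 dB jitter for the
control-substitute fixtures).

## Activity detection and features

A bipolar trace is embedded as its analytic signal (frequency-domain
Hilbert transform); the distance of every sample from the trace centroid
forms a radius distribution whose mean plus one standard deviation is the
activity threshold (edge 50 ms excluded from threshold estimation). The
supra-threshold mask is cleaned by merging gaps under 10 ms and discarding
segments under 5 ms. Detection is invariant to amplitude scaling by
construction.

Seven features feed the classifiers:

* `duration` (ms): the mean first-to-last span of each beat's activity
  cluster (segments closer than 250 ms belong to one beat). In dense
  fibrosis a single activation fragments into several bursts; the
  clinically meaningful quantity is the total activation time of the tissue
  under the electrode, which the cluster span measures and which restores
  the monotonic increase of duration with density that per-fragment
  durations lose.
* `p2p` (mV): mean per-segment peak-to-peak amplitude.
* `samp_en`: sample entropy (m = 2, r = 0.2 SD, Chebyshev metric,
  self-matches excluded).
* `sh_en` (bits): Shannon entropy of the amplitude histogram, 64 equal-width
  bins over the window's own range.
* `sp_en` in [0, 1]: normalized spectral entropy of the Welch PSD
  (256-sample Hann segments, 50% overlap).
* `lz`: LZ76 phrase count of the median-binarized window, normalized by
  `log2(n)/n` (a computable surrogate for Kolmogorov complexity; the
  canonical Kaspar-Schuster parsing is used, under which a constant
  sequence has two phrases).
* `fd`: Higuchi fractal dimension of the whole 2.5 s trace (k_max = 16).

Per-segment estimators on short segments use a window of at least 100 ms
(128 ms for spectral entropy, whose Welch estimator needs 256 samples)
centred on the segment, which stabilizes the estimates.

## Dataset, classifiers, and evaluation

The study dataset (`build_study_dataset()`) combines, at desk scale:

* control tissue at 30 and 40 cm/s, paced from three sites (left border,
  bottom border, top-right corner);
* control-substitute fixtures standing in for clinical high-voltage
  signals: jittered CV (28-42 cm/s), electrode height (0-0.5 mm), SNR
  (15-25 dB), several independent noise draws per simulation, and — like
  the expert annotation they emulate — only signals with p2p > 0.5 mV
  retained;
* fibrotic tissue: the density series (10/20/40/60% at 2 mm) and
  transmurality series (0.5/1/2 mm at 60%), five texture seeds per cell
  crossed with all three pacing sites, at the healthy baseline conduction
  velocity (the two-CV variability belongs to the non-fibrotic class, whose
  amplitude it is meant to spread), 20 dB noise.

Each bipole contributes one labeled feature row. Classifiers are rpart
decision trees (Gini, no depth cap, minimum leaf size 3, deterministic
ties), with greedy forward feature selection: each round drops candidates
correlated above 0.6 (Pearson, training set) with any selected feature and
adds the candidate maximizing validation accuracy, stopping when no strict
improvement remains; ties break by the canonical feature order (duration,
p2p, SampEn, ShEn, SpEn, LZ, FD). Evaluation runs 100 stratified 70/15/15
hold-out realizations (rounding toward training, every class in every
subset, realization k seeded with base + k) and reports mean and standard
error of accuracy, sensitivity and specificity (fibrotic positive for the
binary task, macro-averaged one-vs-rest for the multiclass tasks), plus the
validation-test gap as an overfitting check.

The electrode-height sweep re-synthesizes the electrograms of a reduced
condition set with the electrodes raised (same transmembrane solution,
new Green's-function weights), re-extracts features, and evaluates the
contact-trained tree at each height.

Synthetic substrate maps place circular fibrotic patches of known density
and depth on a planar pseudo-atrium, draw each map point's bipolar trace
from a per-condition simulation bank with a fresh noise realization, and
score classifier calls and the 0.5 mV voltage rule against the stored
ground truth with the Sorensen-Dice index (two empty sets are defined as
similarity 1; a point exactly at the cutoff is labeled high-voltage).

## What the generator does and does not emulate

The generator reproduces: slowed, tortuous conduction and conduction block
through textured collagen; amplitude loss and activity prolongation with
increasing density and transmurality; wavefront-direction and CV effects on
bipolar amplitude; contact-loss degradation with electrode height; colored
catheter noise. It does not emulate: curved atrial anatomy and wall-thickness
heterogeneity, bath loading and metallic-electrode distortion of the
electrogram slope, far-field ventricular activity, biophysically detailed
ionic currents, or real inter-patient variability — the control-substitute
fixtures are simulations with jittered parameters, not recordings. Passing
tests therefore demonstrate that the pipeline recovers the substrate
signatures its own forward model encodes, under realistic noise; they do not
by themselves establish clinical performance.

## Problem sizes and reproducibility

The desk-scale study uses a 16 x 16 x 2 mm patch at 1/3 mm spacing
(13,824 elements; the full 30 x 30 x 2 mm at 0.2 mm is available through
`study_config(full_scale = TRUE)`), a 6.5 mm fibrotic region that encloses
all 16 electrodes, five texture seeds per condition cell, and about one
hundred tissue simulations per dataset. Every stochastic step — texture, splits,
noise draws, substitute jitters — derives from one base seed, and repeated
calls with the same seed are bit-reproducible. `scripts/acceptance.R`
regenerates the dataset and recomputes the headline classifier metrics from
scratch.

## Known limitations

* The reduced ionic model under-represents source-sink safety factor
  effects; near-threshold propagation through very dense textures is more
  fragile than in biophysically detailed models.
* The infinite-medium Green's function ignores the insulating blood-tissue
  interface; amplitudes are calibrated, not predicted ab initio.
* Multiclass accuracy at desk scale stays below the full-scale reference
  values: with a reduced patch, fewer texture realizations, and a single
  catheter, within-class variability (texture sampling per bipole,
  wavefront direction) is proportionally larger. The acceptance suite
  reports the achieved values honestly rather than tuning toward the
  reference.
* The detection rule applies the centroid-radius threshold sample-wise; the
  alternative of thresholding per closed loop is not implemented.
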