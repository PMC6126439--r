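---
title: "Surrogate-driven respiratory motion correction: models, simulator and design choices"
author: "respimoco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-driven respiratory motion correction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Respiratory motion blurs PET images acquired over minutes: a lesion near the
diaphragm rides a ~20 mm superior–inferior excursion every breathing cycle,
so its reconstructed uptake is smeared over that range, SUV metrics drop,
and small lesions can fall below detectability. A second, subtler failure
mode involves attenuation correction: the attenuation map (μ-map) is
acquired in a breath-hold at one respiratory position, and if that position
is extreme, the emission data and the μ-map disagree about where the dense
liver ends and the lung begins, producing the curved intensity bias at the
diaphragm known as the *banana artifact*.

`respimoco` implements, at desk scale, a correction pipeline that needs no
external hardware: the respiratory surrogate is derived from the PET raw
data themselves, a short simultaneous dynamic MR acquisition supplies the
anatomy's motion, a per-voxel linear model links the two, and a
motion-compensated reconstruction uses every acquired count. Because no
clinical data ship with the package, a synthetic breathing-thorax phantom
with *known* ground-truth deformation stands in for the patient; everything
the pipeline estimates can therefore be checked against truth.

# The motion model

For each voxel $x$ and displacement component, tissue displacement is
modeled as linear in two surrogate signals — the respiratory amplitude
$s(t)$ and its time derivative $\dot s(t)$:

$$ d(x, t) = c_0(x) + c_1(x)\, s(t) + c_2(x)\, \dot s(t). $$

The $\dot s$ term encodes *hysteresis*: at equal amplitude, tissue sits at
different positions during inhalation and exhalation, so a function of $s$
alone cannot represent the loop; the signed velocity term can. Because the
model is linear, it interpolates *and extrapolates* to any surrogate value —
including breath-hold positions outside the free-breathing range, which is
exactly what the μ-map correction requires.

Fitting is per voxel by iteratively reweighted least squares with Huber
weights (tuning constant $1.345\sigma$, $\sigma$ from the per-voxel MAD),
which makes the fit robust to occasional registration failures on single
slices; images whose registration residual is an outlier for their slice
position are excluded outright.

## Identifiability of the gradient term

Two facts discovered during development shaped the design and are worth
recording:

1. **A clock error is a hysteresis impostor.** If the surrogate is shifted
   by a small $\delta$ relative to the anatomy,
   $s(t-\delta) \approx s - \delta \dot s$: a phase error aliases directly
   into $c_2$. With a diaphragm amplitude of ~25 units·mm, a 75 ms error
   cancels a 2 mm hysteresis term entirely. The cross-correlation clock
   alignment is accurate to about ±0.05–0.1 s, which is not enough.
   `fit_model()` therefore co-optimizes a residual shift with the model: a
   grid of shifts around the aligned value is scanned, each evaluated by the
   residual of an *amplitude-only* fit on the 300 highest-motion voxels (the
   amplitude-only residual has a single sharp minimum at the true shift,
   whereas scanning with the gradient term present lets $\delta$ and $c_2$
   trade off), and the minimizing shift is refined parabolically and used
   for the final two-surrogate fit.

2. **The PET-derived surrogate inherits the body-average hysteresis.** The
   first principal component of the frame sinograms is driven by the same
   moving anatomy, so it already contains an $\dot s$ admixture with the
   *count-weighted mean* lag of the body. Only spatially *differential*
   hysteresis — organs lagging more or less than that average — is
   identifiable on top of it. A ground-truth generator whose $\dot s$
   pattern is a scaled copy of its amplitude pattern is therefore
   indistinguishable from a time shift; the phantom gives the hysteresis
   term its own spatial envelope (below).

# The synthetic phantom and what it does (not) emulate

The phantom is a 2D coronal slab, 96 × 96 voxels at 3 mm (a config choice;
the operations are dimension-agnostic and the quantification layer also
accepts 3D volumes). Organs are ellipses: body (soft tissue, 1 kBq/mL,
μ = 0.096 cm⁻¹), two lungs (0.3 kBq/mL, 0.03 cm⁻¹), liver (2 kBq/mL), and a
configurable lesion list (default: one 10-mm, 8 kBq/mL lesion at the liver
dome, the highest-motion location). SUV calibration uses 70 kg / 350 MBq.

**Ground-truth motion** is superior–inferior,
$d = g_1(x)\,s + g_2(x)\,\dot s$, with $g_1$ peaking at 20 mm at the
diaphragm (the average diaphragm excursion) and decaying smoothly to zero at
the lung apices, the inferior body edge and the lateral body outline. The
hysteresis field $g_2$ peaks at 3 mm·s and is confined to a 25-mm gaussian
band around the diaphragm — a spatially distinct lag pattern, for the
identifiability reason above, and because diaphragm-adjacent tissue is where
breathing-path hysteresis of several millimetres is actually observed. An
optional *mismatch* mode adds a quadratic-in-$s$ term so that model
misspecification can be studied. A `motionless-null` preset sets both
amplitudes to zero.

**The breathing waveform** is a raised-cosine power,
$s(t) = A_c \sin^{2k}(\pi t / T_c)$ with $k = 2$, giving the long
end-exhale dwell of free breathing ($k=1$ is a pure sinusoid). Each cycle
draws its own amplitude (CV 15%) and period (mean 4 s, CV 10%) — intercycle
variability — and a linear drift is available. These are conventional
values, not measurements.

**PET acquisition** bins the 4-minute window into 0.5-s frames (which
resolve 4-s cycles), warps activity and μ-map to the frame-midpoint state,
forward-projects with attenuation (ideal 2D parallel beam, 84 angles;
optional 4.5-mm FWHM radial PSF reflecting the scanner's stated intrinsic
resolution), adds a known uniform background standing in for randoms plus
scatter (10% of trues — the estimation of these terms is deliberately out
of scope, so the reconstruction receives the background as a known additive
term), and Poisson-samples. The calibration factor (0.3 counts per
kBq/mL·mm·s, about 2 × 10⁷ counts per 4-min study) was chosen so that the
slab's count level plays the role of a clinical axial FOV; an order of
magnitude fewer counts starves the PET-derived surrogate of SNR.

**Dynamic MR** takes 200 snapshots over 1 minute (0.3 s each), cycling 9
nominal sagittal slice positions. In the 2D slab geometry all positions view
the same coronal plane; the position index preserves the acquisition's
timing and grouping structure (per-position references, per-position
registration) without pretending to model through-plane sampling. The MR
clock runs at a configurable rate relative to the PET clock with an offset
that the alignment step must recover. Organ contrast is an arbitrary
per-organ intensity map with mild gaussian noise — no MR physics.

What passing tests on this phantom *do* show: the estimator chain
(surrogate → alignment → registration → robust fit → gated MCIR with warped
μ-maps) recovers known deformations, restores lesion quantification, and
removes attenuation-mismatch artifacts under realistic noise. What they do
*not* show: performance under real anatomy (sliding organ interfaces, bulk
motion, cardiac motion), real MR contrast and slice geometry, real
scatter/randoms physics, or clinical effect sizes — the clinical
SUV/detection gains reported for patient cohorts are properties of patient
data and are not reproduced here.

# Pipeline stages and their numerical choices

* **Surrogate** (`extract_surrogate`): first principal-component score of
  the mean-centered frame sinograms (center-of-mass fallback), sign-locked
  to a superior–inferior center-of-mass proxy so repeated runs cannot flip,
  Savitzky–Golay smoothed (window ≈ 1.5 s, order 3), min–max normalized to
  [0, 1] *per window* (not per cycle), then differentiated by central
  differences. Normalization precedes differentiation. A flat signal
  (motionless, noiseless) is flagged degenerate and returned as all-zero.
* **Clock alignment** (`align_clocks`): maximizes |correlation| between the
  interpolated PET surrogate and a per-image diaphragm-edge trace from the
  MR (gradient-centroid, sub-voxel; standardized per slice position), grid
  search ±10 s at 0.1 s with parabolic refinement; the rate factor can be
  co-estimated on a 2D grid. The residual shift is later re-refined inside
  the model fit (above).
* **Registration** (`register_pair`, `register_slices`): multi-resolution
  additive demons (3 levels, gaussian field regularization σ = 1.5 voxels),
  no sliding-interface model. Per slice position the reference is the image
  whose aligned surrogate is closest to the modal end-exhale value with
  small |ṡ|. Identical images give an exactly zero field — which is what
  makes the motionless null test exact. Outliers: residual beyond
  median + 5·MAD for the position.
* **Gating** (`make_gates`): default 8 gates — frames split by sign of ṡ
  (inhale/exhale), then equal-count amplitude quantiles within each
  direction; representative state is the count-weighted mean (s, ṡ). Every
  frame belongs to exactly one gate, so gating is a partition and 100% of
  counts enter the corrected reconstruction (asserted at run time).
* **Reconstruction** (`osem`, `recon_motion_corrected`): OSEM with 21
  subsets (bit-reversed angle allocation), 3 iterations, 4-mm gaussian
  postfilter. The motion-corrected mode is MCIR: one reference-state image,
  each gate modeled as the attenuated projection of the warped reference
  (sparse bilinear warp matrix inside the system model; its exact transpose
  in the backprojection — the adjoint, not the inverse warp).
  The μ-map is first mapped from its recorded breath-hold state to the model
  reference (predicted field inverted by fixed-point iteration, 25 steps)
  and then warped to each gate. Reconstruct-transform-average is available
  as `mode = "rta"` for comparison; it needs inverse fields and is not the
  default. Zero-sensitivity voxels are excluded from updates rather than
  divided by. With a zero-motion model and any gating, MCIR reduces
  algebraically to the pooled uncorrected reconstruction (the per-gate
  durations cancel), which the null test verifies to < 1e-6.
* **Quantification** (`suv_peak`, `suv_max`, `delta_suv`): SUV = kBq/mL ×
  kg / MBq. SUV_peak is the maximum 12-mm-sphere mean over sphere centers in
  the ROI; the sphere is discretized by voxel centers within 6 mm (a disk in
  2D) and clipped at grid edges; it is asserted equal to an exhaustive
  brute-force sweep. "Considerable" change = both ΔSUV metrics beyond ±5%,
  with the uncorrected value as denominator (undefined when it is 0).
* **Reader statistics** (`match_marks`, `detection_summary`,
  `wilcoxon_signed_rank`, `paired_t`): greedy nearest one-to-one mark
  matching with a 15-mm tolerance (the tolerance is a package choice; human
  readers matched visually); unmarked reference lesions are false negatives
  scored χ = 0. The signed-rank test enumerates all 2^m sign assignments
  for m ≤ 12 non-zero pairs (ties get average ranks; zeros dropped by
  default, Pratt handling available) and otherwise uses a normal
  approximation with continuity correction; all tests are two-sided.

# Problem sizes used by the test and acceptance runs

The shipped tests and `scripts/acceptance.R` run the full study conditions
(96 × 96 at 3 mm, 240 s of PET at 0.5-s frames, 60 s of MR, 8 gates, OSEM
21 × 3 × 4 mm) for the end-to-end properties, and a compact 48 × 48
geometry for unit-level checks of the orchestration. Seeded repetition
counts (20 for the direction-of-effect property, 5 for the hysteresis
comparison and the acceptance script's SUV panel) are the package's chosen
simulation sizes.

# Known limitations

* 2D reconstruction geometry; through-plane motion and slice gaps are not
  modeled (the quantification layer is 2D/3D-agnostic).
* The demons registration has no sliding-motion model, so lung/chest-wall
  sliding — absent from the phantom — would be smoothed over.
* Scatter and randoms are a known uniform background, not estimated.
* The μ-map's surrogate value is taken as observed (the simulator converts
  the true breath-hold state to the estimated surrogate scale through the
  recorded frame states), emulating the clinical situation where the
  PET-derived signal is available during the breath-hold.
* The fitted model's coefficients live on the normalized surrogate scale;
  they equal the generator's divided by the normalization slope, so
  coefficient comparisons against truth must account for that scale (the
  tests do).
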