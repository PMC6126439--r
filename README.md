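# respimoco

Surrogate-driven respiratory motion correction for simultaneous PET/MR, at
desk scale, with a synthetic breathing-thorax phantom as ground truth.

## The problem

PET acquisitions last minutes; the diaphragm moves ~20 mm with every breath.
Lesions in the liver dome and lungs are smeared along that excursion, their
SUV drops, and small foci can become undetectable. A second failure mode is
attenuation: the μ-map comes from a breath-hold acquisition at one
respiratory position, and if that position is extreme, the emission data and
μ-map disagree at the lung/liver boundary, producing the curved "banana"
bias at the diaphragm.

`respimoco` implements a correction pipeline that needs no external
hardware, for researchers who want to study its estimator chain end to end
against known truth:

1. a respiratory surrogate s(t) and its gradient ṡ(t) derived from the PET
   frame data alone (first principal component of the frame sinograms);
2. temporal alignment of the PET and MR clocks (time shift, optional rate
   factor) by correlation with a diaphragm trace from a 1-min dynamic MR
   acquisition;
3. deformable registration of the dynamic MR images to an end-exhale
   reference, then a per-voxel **two-surrogate linear motion model**

   d(x, t) = c₀(x) + c₁(x)·s(t) + c₂(x)·ṡ(t)

   fitted by Huber-weighted IRLS (robust to per-slice registration errors),
   with the residual clock shift co-optimized in the fit. The ṡ term
   captures hysteresis (different inhale/exhale paths); linearity gives
   interpolation *and* extrapolation to any respiratory state, including
   breath-hold positions outside the free-breathing range;
4. amplitude/direction gating of the PET frames (a partition — 100% of the
   counts are used) and **motion-compensated OSEM** (21 subsets, 3
   iterations, 4-mm gaussian postfilter): the warp sits inside the system
   model with its exact adjoint in the backprojection, and the μ-map is
   mapped from its breath-hold state to the model reference and warped to
   each gate;
5. quantification: SUV_peak (12-mm sphere), SUV_max, ΔSUV with the >5%
   "considerable" rule, reader-score (χ) analytics with TP/FP/false-negative
   matching, exact Wilcoxon signed-rank and paired t tests.

Everything runs on a synthetic 2D thorax phantom (organs, lesions, known
parametric deformation driven by a variable breathing waveform), so every
estimate the pipeline produces can be compared against ground truth.

## Worked example

```r
library(respimoco)

report <- run_experiment(preset_config("baseline-moving-lesion"), seed = 1)
print(report)
#> <experiment_report> baseline-moving-lesion (seed 1 )
#>   model: max|c1| = 25.9 mm, max|c2| = 1.907 mm
#>   clock alignment: tau = -0.03168 s
#>   gating: 8 gates, counts conserved: TRUE
#>   lesion dSUV_peak: 30.03 % ; dSUV_max: 46.2 %

report$suv$uncorrected$suv_peak      #> 0.865  -- motion-blurred lesion
report$suv$motion_corrected$suv_peak #> 1.125  -- after correction
report$suv$reference$suv_peak        #> 1.171  -- motion-free reconstruction
```

The 10-mm liver-dome lesion rides a ~17 mm excursion; uncorrected, its
SUV_peak is depressed by roughly a third. The corrected reconstruction —
which uses all acquired counts and a motion model fitted entirely from the
simulated PET/MR data — recovers to within a few percent of the motion-free
reconstruction. `max|c1|` is the fitted amplitude coefficient on the
normalized surrogate scale (the generator's 20 mm divided by the
normalization slope), and τ is the recovered PET↔MR clock shift (none was
injected here).

The μ-map misalignment study (`preset_config("mumap-misalignment")`, a
deep-inhale breath-hold at s = 1.2) reproduces the diaphragm-band artifact:
a ~50% negative bias band in the uncorrected image that model-warped
per-gate μ-maps reduce by about an order of magnitude.

A thin CLI wrapper is included:

```sh
Rscript inst/cli/respimoco.R run --preset baseline-moving-lesion --seed 1 --out out/
```

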