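---
title: "Models, methods and design choices in infantdot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, methods and design choices in infantdot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`infantdot` simulates and analyzes high-density diffuse optical tomography
(HD-DOT) recordings of infant responses to blocked emotional speech. This
vignette is the package's account of the science it implements: the forward
and inverse models, the statistical procedures, the synthetic-data generator
that stands in for real infant recordings, and the places where the design
was genuinely open and a choice had to be made. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The forward model

The phantom is a voxelized slab: planar scalp, skull and CSF shells over a
thick gray-matter layer, white matter below, on a 40×40×40 grid of 2 mm
voxels by default (the native 1 mm resolution of an anatomical image is
supported by `voxel_size_mm = 1`; 2 mm keeps desk-scale runs fast). Layer
thicknesses (scalp 2, skull 2, CSF 1, gray 20 mm) are chosen so that brain
tissue starts about 5 mm below the surface, which is characteristic of young
infants and is why DOT works so well in this population. Head-size variation
across subjects is reduced to the single `voxel_size_mm` scale factor;
marker-based surface fitting is out of scope.

Per-tissue absorption and reduced scattering coefficients are configuration
values carried in the head-model object, with defaults in the physiological
range for near-infrared light (~798 nm, near the hemoglobin isosbestic
point, where a single wavelength suffices to image total hemoglobin). They
are placeholders in the sense that no downstream result is anchored to their
exact values.

Light propagation uses the continuous-wave diffusion approximation in a
homogeneous semi-infinite medium with an extrapolated boundary
(`zb = 2AD`), with effective optical properties taken as the
volume-weighted average over tissues. Sources and the adjoint detectors are
buried one transport mean free path (`1/μs'`) below the surface. The
channel-by-voxel sensitivity (Jacobian) is the Rytov product

    J[i, v] = Φ_src(v) Φ_det(v) V_vox / Φ_src(det)

so that `J %*% Δμ_a` is the first-order change in −log amplitude. A
full photon-transport Monte Carlo would be the reference method for a real
layered head; here the analytic Green's functions give a deterministic,
seconds-fast forward model adequate for validating the pipeline, and a
small random-walk Monte Carlo (run once; its result is frozen in the test
suite) confirms that the depth profile of the sensitivity agrees with
photon transport at the 8 mm scale. Negative lobes from the image source,
which are a numerical artifact of evaluating the two-point formula on
voxels above the source depth, are clipped to zero.

The probe is 15 sources and 15 detectors. Two layouts are provided:
a checkerboard (minimum separation = the 13 mm pitch) and the default
"offset" double-density layout in which the detector grid is shifted half a
pitch diagonally, creating short channels at 13/√2 ≈ 9.2 mm. Short channels
(< 12 mm) sample mainly scalp, and the superficial-signal-regression stage
requires them, so the offset layout is the study default. Channels are
enumerated up to 45 mm separation. The field of view (FOV) is the set of
gray/white voxels with relative sensitivity above 0.001 (per channel the
Jacobian is normalized by its within-brain maximum, then the per-voxel
maximum over channels is taken); a subject-count rule (`min_subjects`) is
available for multi-subject FOV intersection.

## Stimuli and hemodynamics

A run is a randomized sequence of 11 s blocks, four speech conditions
(neutral, happy, angry, sad), separated by rests drawn uniformly from
20–30 s; the default of 6 blocks per condition gives roughly 15 minutes of
recording, a realistic infant session length. Within a block, four phrases
(2.2 s each, 0.7 s gaps — the timing is configurable since only the 11 s
envelope is fixed) drive a boxcar train whose amplitudes habituate as
1, 0.6, 0.3, 0.2; an alternative single-boxcar block mode exists because
the convolution could also be read as treating the block as one epoch, and
the four-boxcar reading is the default.

The canonical adult double-gamma HRF (response delay 6 s, undershoot delay
16 s, unit dispersions, response:undershoot ratio 6) is used as the shape
reference — these are the de facto canonical defaults. HbO₂ uses the kernel
shifted −1 s (HbO₂ leads), HbR is the unshifted kernel scaled by −1/6, and
HbT = HbO₂ + HbR pointwise. The absolute amplitude scale is a free
parameter; plots and simulated responses are in arbitrary units unless a
concentration scale is supplied.

## The synthetic-data generator

`generate_recording()` emulates the statistical structure of real infant
recordings, in log-amplitude per channel:

* activation: per-condition Gaussian blobs (µM HbT at peak, supported on
  gray matter) modulated by the simulated block HbT course and converted to
  absorption via the Beer–Lambert extinction coefficient, then forward
  projected through J;
* global physiology: one band-limited (0.01–0.1 Hz) signal shared by all
  channels, coupled as `exp(−SDS/15 mm)` so short channels carry more —
  this is what makes SSR meaningful;
* slow polynomial drift per channel, an aliased ~1.1 Hz cardiac line
  (the 1.2 s frame interval aliases it, as in real frame-scanned systems),
  and white photon noise in log-amplitude;
* movement artifacts: Poisson-distributed (default 0.4/min), 1–3 s long,
  spiky broad-band transients at 10× the background SD, each with a
  ground-truth annotation (the synthetic stand-in for video coding of
  infant movement).

Amplitudes are generated on the native 1.2 s frame grid with per-source
scan offsets (sources fire sequentially within a frame), so resampling to a
common time base downstream does real work. Everything is reproducible from
a single seed.

The artifact rate of 0.4/min was chosen once so that, with the ≥ 5
clean-repetitions-per-condition inclusion rule, roughly half of simulated
subjects fail inclusion — matching the attrition that infant NIRS/DOT
studies typically report (the study design this emulates analyzed 21 of 46
measured infants). The end-to-end validation mirrors that design by
generating subjects until 21 pass inclusion.

What the generator does **not** emulate: real scalp-coupling optics,
wavelength-dependent chromophore separation (a single isosbestic-adjacent
wavelength and HbT-only reconstruction are assumed throughout),
subject-specific anatomy, sleep-state effects, and spatially structured
physiology beyond the single global component. Passing tests therefore
demonstrate the correctness and calibration of the pipeline, not the
statistical power one would obtain on real infant data.

## Preprocessing

Resampling is per-channel linear interpolation onto a shared 1 Hz grid
(exact on affine signals; on a sinusoid of frequency f the error is bounded
by `h²(2πf)²/8`). An upsampling guard rejects target rates more than 10×
the native rate.

The bandpass contract is stated in terms of the measured response, not the
filter family: a zero-phase (forward–backward) filter whose measured gain is
−3 dB ± 0.5 dB at 0.007 and 0.2 Hz and 1 ± 0.05 in the passband. The
implementation is a second-order Butterworth high-pass and low-pass pair
applied with `filtfilt`; because two passes square the magnitude response
and the bilinear transform warps the frequency axis, the design cutoffs are
calibrated numerically (by root-finding on the analytic two-pass gain) so
the measured −3 dB points land exactly on the nominal edges.

SSR subtracts each channel's least-squares projection onto (intercept,
short-channel mean). Residuals are exactly orthogonal to the regressor, the
step is idempotent, and a degenerate all-zero regressor reduces to mean
centering. Note one consequence visible in noise-free simulations: when
there is no physiological noise the short channels contain only stimulus
signal, so SSR cancels a large part of the activation. This is why the
end-to-end validation calibrates the pipeline's contrast gain by a paired
difference of two identically-seeded runs (with and without the planted
blob) rather than by a noise-free run.

Artifact detection compares each channel's high-pass-filtered signal (the
band low edge, 0.007 Hz, is reused as the cutoff; the detection threshold is
what matters, not this cutoff) against k× its own standard deviation
(per-channel SD is the conservative reading of "the signal"), unions the
result with externally annotated intervals, and reports the chosen k. In
automatic mode k is scanned over [3.5, 7] and the knee of the
(k, flagged-count) curve — the point of maximum distance from the chord, a
standard L-curve operationalization chosen here since the original
procedure combined the threshold with visual evaluation — is selected.
Stimulus epochs ([−1, 18] s around onset, covering baseline through the
analysis window) that touch any masked sample are excluded, and a subject
is included only if every condition keeps at least 5 clean repetitions.

## Response estimation

Responses are estimated by FIR least-squares deconvolution: one lagged
onset indicator per condition and lag on [−5, 30] s at 1 Hz, block-train
onsets only (one event per block, matching the single-epoch treatment of
the four-phrase train), ordinary least squares per channel, masked samples
dropped as rows (interpolating them would leak artifact energy into the
estimate). With non-overlapping epochs and no noise the estimator equals
the trigger-locked epoch average exactly, which anchors its correctness; an
FIR design was chosen over a parametric HRF basis because the infant
response shape is precisely what one does not want to assume. Baseline
correction subtracts the [−1, 0] s mean; the response magnitude is the
arithmetic mean over lags in [2, 18] s inclusive.

## Image reconstruction

The inverse problem is `argmin_x ‖Jx − y‖² + λ(‖Lx‖² + δ‖x‖²)` with L the
6-neighbor graph Laplacian over brain voxels (reflecting boundary: edges
exist only between brain voxels). The tiny ridge δ = 10⁻⁶ makes the
penalty strictly positive definite — the Laplacian alone annihilates
constants — and with it the solution can be written by the push-through
identity as

    x = R⁻¹ J' (J R⁻¹ J' + λ̃ I)⁻¹ y,   R = L'L + δI,

which factors once and then solves any number of right-hand sides (lags ×
conditions × subjects) at negligible cost. When the brain voxel set fills a
complete axis-aligned box — true for the slab phantom — R is a Kronecker
sum and diagonalizes in the cosine basis, so `R⁻¹` applies spectrally in
milliseconds; for general voxel sets a sparse Cholesky is used, and the two
paths agree to machine precision (cross-checked in the tests). λ is
expressed relative to the mean diagonal of the dual operator `J R⁻¹ J'`
(making it dimensionless and transferable across grids); the default 0.01
was fixed on noise-free fixtures as the smallest value that visibly
suppresses noise without displacing a planted blob's peak, and no automatic
λ selection is enabled by default. Absorption converts to concentration by
ΔHbT [µM] = Δμ_a / ε_HbT × 1000 with ε_HbT in 1/(mM·mm).

Before clustering (and only there — magnitudes for the global and ROI
analyses stay unsmoothed), images are smoothed with a mask-normalized
Gaussian of radius 1.5 voxels. "Radius" is read as the Gaussian σ, with a
FWHM reading available by configuration, since the term is ambiguous and σ
is the conservative (wider) choice. The normalization (smoothing the masked
image and dividing by the smoothed mask) preserves constants on the mask
and preserves the mass of interior features.

## Group statistics

The **global analysis** restricts to gray-matter FOV voxels whose group-mean
magnitude is positive for at least one condition (computed on unsmoothed
group means — whether the original outline used smoothed maps is unstated,
and the unsmoothed reading is logged in the result object), averages each
subject over that mask, and runs: a two-tailed one-sample t-test of the
across-condition average versus zero, Bartlett's test of the equal-variance
assumption, a one-way ANOVA across conditions, Tukey–Kramer post hoc tests
when ANOVA p < 0.05, and per-condition t-tests versus zero. The default
ANOVA treats subjects as independent replicates per condition (the classic
one-way layout); a repeated-measures variant is available by configuration.

**Adaptive voxel-based clustering** thresholds the voxelwise p-map at
p < 0.001 to form seed components (6-connectivity by default,
26-connectivity by option), grows each seed geodesically inside the
p < 0.0033 and p < 0.01 superlevel sets (region growing from the seed, not
the whole superlevel component — the most literal reading of "expanded to
include neighboring voxels", and the rule that also settles how overlapping
expansions are attributed), merges seeds whose grown regions intersect at
any level, re-tests the cluster-mean magnitude per subject at each level
with the same group test, takes the smallest p over levels as the cluster
p-value, discards clusters below 200 voxels at the chosen level (diffuse
optics cannot produce genuinely tiny activations, so small clusters are
edge artifacts), and Bonferroni-corrects with N = 120 — the number of
practically separable measurement channels, the more conservative of the
two published estimates of the method's effective number of comparisons.
Zero-variance voxels receive p = 1 with a warning.

The supported voxelwise tests are the speech-average versus zero t-test,
the one-way ANOVA across conditions, and each condition versus baseline
(baseline is already subtracted, so this is a one-sample t-test; "two-way
Student's t-test" in the source tables is read as two-tailed one-sample).

**ROI analysis** uses six left-hemisphere regions (aSTS, STG, IFG, AI, MI,
pSTS) at infant-template coordinates, realized as 8 mm spheres (the
template gives centers only; 8 mm matches the method's ~1 cm resolution)
intersected with gray matter. The template-to-phantom mapping is an affine
declared in configuration; the default maps template left-lateral depth
onto slab depth so all six centers land in gray matter under the probe.
Per ROI: per-condition means, two-tailed one-sample t-tests versus
baseline, ANOVA with Tukey–Kramer when p < 0.05, and Bonferroni flags for
the six regions. ROIs partially outside the FOV are reported with their
coverage fraction and a warning.

The Tukey–Kramer implementation uses the studentized-range distribution
with the Kramer standard error for unequal group sizes; for two groups it
reduces to the pooled t-test through `q = √2 |t|`, and the tests verify it
against `TukeyHSD` as an independent reference.

## Validation design and problem sizes

Two package-level validation functions define the recovery claims:

* `simulate_null_fwer()` — 200 simulated null studies (21 subjects ×
  4 conditions of iid Gaussian magnitude maps on the brain voxels, smoothed
  like real images) through voxelwise testing and adaptive clustering; the
  familywise error rate (any corrected-significant ≥ 200-voxel cluster) is
  required to stay at or below 0.075. With the extent rule and N = 120 the
  procedure is conservative; observed rates near zero are expected.
* `planted_effect_study()` — the full end-to-end recovery: a happy-condition
  blob (σ = 8 mm) at the anterior STS template center, planted at 3× the
  between-subject SD of the reconstructed magnitude at that voxel. The SD
  is measured from a null study at run time, and the pipeline's contrast
  gain from a paired (identically seeded) run with and without a reference
  blob sharing one artifact mask, so the planted effect size is calibrated
  in reconstructed-image units rather than assumed. Subjects are generated
  with the full noise model until 21 pass inclusion (mirroring
  measured-versus-analyzed attrition), and the claim is that the ANOVA
  clustering reports a corrected-significant cluster whose Tukey–Kramer
  post hoc flags happy > neutral, with the same contrast flagged in the
  anterior-temporal ROI table.

Default problem sizes — the 40³ grid at 2 mm, 138 channels, 6 blocks per
condition, 200 null replicates, 21 analyzed subjects — were chosen as the
smallest configuration that exercises every stage at realistic
dimensionality; the whole validation runs in minutes on one CPU.

## Known limitations

* The analytic semi-infinite forward model ignores the curvature and layered
  heterogeneity a segmented-MRI Monte Carlo model would capture; absolute
  sensitivities (and hence reconstructed amplitudes) are approximate even
  though the pipeline around them is exact.
* Single-wavelength HbT only; no HbO₂/HbR separation, no phase (frequency-
  domain) data.
* The slab phantom's brain is a box; the spectral reconstruction fast path
  exploits this, and curved-anatomy voxel sets fall back to the slower
  sparse factorization.
* Familywise error control is Bonferroni with a fixed N; no permutation or
  random-field alternative is provided.
* The generator's artifacts are exchangeable across channels; real infant
  movement produces spatially structured, optode-specific artifacts.
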