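---
title: "Centrality mapping and behavioural scoring for longitudinal motor learning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality mapping and behavioural scoring for longitudinal motor learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorecm)
```

## The scientific problem

Learning a motor sequence changes the brain's resting-state functional
organisation, but only a control group matched for motor *execution* lets one
separate sequence-specific plasticity from the generic effects of repeated
movement. The design this package analyses is a two-group longitudinal study:
a learning group trains a complex pinch-force sequence (LRN) while a control
group performs a matched simple sinusoidal sequence (SMP), over five training
days plus a familiarization day and a retention probe twelve days later.
Resting-state BOLD is acquired at five of those sessions; behaviour is scored
on every training day.

The analysis chain has four stages, each a module of this package:

1. **Behavioural scoring** of the continuous force-tracking task: temporal
   synchronization (SYN) and lag-aligned root mean squared error (RMSE),
   aggregated and fed into a mixed repeated-measures ANOVA with Tukey post
   hocs.
2. **BOLD cleaning**: initial-volume removal, confound regression (12 motion
   regressors, spike indicators, component-based tissue noise), detrending,
   variance normalization, 0.01–0.1 Hz band-pass, 2.4 mm FWHM mask-aware
   Gaussian smoothing.
3. **Eigenvector centrality mapping (ECM)**, voxel-as-node, computed
   matrix-free by power iteration.
4. **Group-by-time interaction inference** on per-subject centrality change
   maps across learning stages, with permutation cluster-level FDR and a
   formalized sequence-specificity criterion.

Because raw data of this kind cannot be redistributed, the package ships
synthetic-data generators whose defaults encode the study conditions, so the
entire chain is testable end to end.

## Behavioural scoring

A trial is 18 s of force sampled at 80 Hz, displayed as a bar whose height
the participant matches to a reference bar moving between 5% and 30% of the
participant's maximum voluntary force.

**SYN** is the lag (ms) maximizing the Pearson cross-correlation between the
reference (REF) and produced (FOR) traces, evaluated at integer sample lags
within ±3 s (configurable). Zero denotes perfect timing; positive values mean
the participant trails the reference. We use Pearson normalization at each
lag over the overlapping support, no sub-sample interpolation (12.5 ms
granularity at 80 Hz), ties broken toward the smaller absolute lag and then
toward the positive lag. **RMSE** is computed after shifting FOR by the
estimated lag: `sqrt(mean((REF - aligned FOR)^2))` over the overlap. The
published description of the RMSE computation is internally inconsistent
("square rooted and averaged … the square root was then used"); we implement
the standard root-mean-square of deviations, which is what the name denotes.

Trials with zero variance or less than 50% alignment overlap raise a typed
`degenerate_trial` condition; they are flagged and excluded from means, never
silently scored.

**Outlier rule.** A subject is excluded when a day-mean deviates from the
group mean by more than 2 group SDs on at least 2 days (either metric,
assessed within group × condition cells). "On 2 days" is read as "on ≥ 2
days" — the conservative reading.

**Statistics.** The baseline comparison is a Welch two-sample t test on
first-block simple-sequence means (the variance assumption is unstated in
behavioural reports of this kind; Welch is the safer default). The main
model is a split-plot ANOVA with the within factor *day* and a between
factor over **three performance-trace types** — the learning group's complex
trials, the learning group's simple trials, and the control group's simple
trials. The three-level coding is the default because the published group
effect carries 2 numerator degrees of freedom with 60 units, which only a
three-trace coding produces; a plain two-group coding is available
(`coding = "group2"`). Sphericity is assessed with Mauchly's test (the
chi-square approximation mirrors the reference implementation in base R,
second-order term included); when it rejects at 0.05, within-effect degrees
of freedom are multiplied by the Greenhouse–Geisser epsilon if it is below
0.75 and by the Huynh–Feldt epsilon otherwise. Effect sizes are partial
eta-squared. Post hoc comparisons between consecutive days use Tukey's HSD
on a subject-blocked design, per trace type; confidence intervals everywhere
use t quantiles (small n), not 1.96.

## Synthetic behavioural data

`gen_ref_lrn()` builds the complex reference sequence as a natural spline
through pseudo-random target heights that alternate between the upper and
lower halves of the force range, then rescales it with a monotone two-piece
map pinning the minimum, maximum and *mean* of the trace. Pinning the mean
matters: the simple control sequence is a sinusoid, and a sinusoid's mean is
the middle of its range, so a reference whose mean strays from mid-range
could not be matched on both its range and its total force. The true
published sequence heights are not public; only the matched properties drive
the analysis, so the generator reproduces properties, not values.

`gen_ref_smp()` constructs the control sinusoid from four constraints:
frequency of maximum spectral power (estimated with a Hann window and
parabolic interpolation of log power, so frequencies between FFT bins are
recovered), identical duration, identical min/max, and total force matched
through a joint phase/offset optimization. Each deviation is reported and
checked against a tolerance (default 2%); failure is an error, never a
silent mismatch.

`gen_for_response()` is the forward model the scorer must invert: the
reference delayed by a planted lag (edges held, avoiding wrap-around
artifacts that would bias lag recovery), scaled, plus Gaussian noise,
clipped to the display range. `gen_behaviour_cohort()` arranges trials in
the published block structure (3 blocks/day; learning group 3 simple + 3
rest + 3 complex trials per block; control group replaces complex with
simple trials, matching total effort, i.e. 9 trials per condition per day)
with per-(group, condition, day) lag schedules. The default schedule plants
steeply decreasing lags over days 1–3 for the learning group's complex
trials and flat lags for the control group — the qualitative pattern of
sequence-specific learning; magnitudes (150→60 ms; 25 ms between-trial SD;
1.5% force noise) are chosen once as plausible values and are configurable.

## BOLD cleaning

Cleaning per in-mask voxel proceeds in a fixed order: confound regression →
linear detrend → variance normalization → zero-phase order-4 Butterworth
band-pass (0.01–0.1 Hz by default, cutoffs interpreted against 1/TR) → final
re-standardization. The published description lists the steps in one
sentence without an order; regressing before filtering avoids confound
leakage through filter mismatch, and the final re-standardization restores
the unit-variance contract that filtering would otherwise perturb. Filtering
uses full-length odd-reflection padding to suppress edge transients on short
series. Note the cleaning is deliberately *not* idempotent to machine
precision: a Butterworth band-pass is not a projection, so re-cleaning
changes in-band content by order 1%; tests assert stability (correlation >
0.98), not exact idempotence.

Confounds comprise the 6 motion parameters and their first derivatives,
one-hot spike regressors for volumes whose composite motion (frame-to-frame
parameter differences, rotations converted to mm at a 50 mm radius) or
global signal exceeds a z threshold (default 3, configurable — the original
artifact-detection thresholds are not published), and component-based
physiological regressors: within each tissue mask the top-variance voxels
(top 2%) are detrended, standardized, and their first 5 left singular
vectors retained. Collinear confound columns are dropped with a warning;
voxels fully explained by confounds are flagged degenerate and removed from
the mask.

Smoothing is a separable Gaussian at 2.4 mm FWHM,
`sigma = fwhm / (2 sqrt(2 ln 2)) / voxel_size`, applied mask-aware: data and
mask are smoothed with the same kernel and divided, so voxels near the mask
boundary are not dimmed. `fwhm = 0` is the identity.

Out of scope by design: motion correction, fieldmap undistortion,
segmentation and template registration — these require real scanner data and
external toolchains; phantoms are generated already aligned on a shared
grid. No slice-timing correction is applied (short TR).

## Eigenvector centrality

Every in-mask voxel is a node; the similarity between two voxels is their
timecourse Pearson correlation rescaled as `M = (C + 1) / 2`, which makes
all weights nonnegative so the dominant eigenvector is unique and
nonnegative (Perron–Frobenius) whenever `M` is irreducible. The published
analysis names the fast ECM approach without printing the rescaling; the
`(C+1)/2` device is that algorithm's standard choice and is the default
here, with `|C|` exposed as an option.

The dominant eigenvector is found by power iteration without materializing
the voxel-by-voxel matrix: with `Z` the t × V matrix of z-scored
timecourses, `M v = (Z'(Z v)/T + sum(v))/2`. Correlation uses population
normalization (divide by T); any consistent normalization cancels in the
eigenvector, which a test asserts. Iteration starts from the uniform
positive unit vector — deterministic, and inside the positive cone — and
stops when the L2 change falls below `tol` (default 1e-9, max 1000
iterations). Non-convergence returns `converged = FALSE` with a warning
rather than an error; the per-iteration Rayleigh quotients are returned so
slow convergence from near-degenerate spectra is visible rather than
silent. A dense eigendecomposition oracle (`dense_ecm()`, guarded to ≤ 5000
voxels) validates the matrix-free route to 1e-6 in the test suite across
varied correlation structures.

EC maps are unit-norm over the mask and nonnegative; change maps
(`ec_delta()`) subtract sessions on the intersection mask.

## BOLD phantoms

`gen_bold_cohort()` plants a known group-by-time effect: four cubic regions
inside a spherical brain mask (a hub, an effect region, two controls), plus
white-matter and CSF corner compartments with their own structured noise.
Per session, band-limited (0.01–0.1 Hz, so cleaning does not destroy the
planted structure) latent region signals are drawn with empirical
inter-region correlations *exactly* equal to the target matrix (QR
orthonormalization followed by a Cholesky transform); voxel timecourses are
latent signal plus white noise. The default effect ramps the learning
group's hub↔effect-region correlation linearly in day number from 0.6 on
day 1 to 0.2 on day 5 (constant outside that span), while every control
correlation and the control group's matrices stay fixed — a planted
sequence-specific centrality decrease during overall learning.

Defaults scale the acquisition to desk size while keeping the physics
meaningful: 24³ grid, 200 volumes, TR 1.13 s (so the band-pass edges are
real frequencies), 1.2 mm voxel labels. Region voxels carry a 2:1
signal-to-noise ratio — chosen once, as the regime the phantom represents:
region-structured connectivity clearly present at the per-voxel level yet
noisy enough that subject-level variability is realistic. The phantom
deliberately omits hemodynamics (no HRF), scanner artifacts and
distortions; passing tests therefore demonstrate the pipeline's statistical
behaviour, not robustness to acquisition physics.

All generators are pure functions of their arguments including the seed;
one master seed drives derived per-stream seeds.

## Interaction inference and sequence specificity

Learning stages map to day pairs — fast (d1, d2), slow (d2, d5), overall
(d1, d5), retention (d5, d17) — each tested in both directions, giving
eight directional contrasts. For a balanced two-group two-occasion design
the factorial group-by-time interaction equals a two-sample t test on
per-subject change maps, which also permits exact group-label permutation;
the package therefore tests `ΔEC` between groups per voxel (pooled t,
df = n1 + n2 − 2), signed so positive t matches the contrast direction
relative to the learning group. Baseline (pre-training) group differences
are checked with a two-sided voxelwise t test through the same cluster
machinery.

Cluster inference thresholds at the one-sided t quantile of the primary
p (default 0.001), forms connected components (18-connectivity by default;
6 and 26 selectable), and draws the null from group-label permutations,
pooling all suprathreshold cluster sizes across permutations; each observed
cluster gets `p = (1 + #null ≥ K) / (1 + #null)` and Benjamini–Hochberg FDR
is applied across observed clusters (cluster-level FDR at 0.05). When the
number of distinct labelings is at most 10,000 the null is enumerated
exactly; otherwise `n_perm` draws are used (default 1000). This permutation
null is a deliberate, documented substitution for random-field-theory
cluster p-values, which are out of scope.

For each significant cluster, per-group trajectories (mean, SEM, t-based
95% CI of in-cluster mean EC per day and of the stage's change) determine
**which group drives the effect**: among groups whose CI for the change
excludes zero, the larger absolute mean change wins (none if neither; if
both, the larger magnitude wins and the tie is recorded). The effect is
**sequence-specific** exactly when the learning group drives it *and* the
control group's CI contains zero — a formalization of "driven by the
learning group with little to no change in the control group". The informal
"little to no change" has no published quantitative form; the CI-based
reading is validated in the test suite against the published labels of all
eight reported region-by-stage summaries (one sequence-specific region —
right SMA during overall learning — and seven control-driven effects),
which it reproduces exactly, including the tie-break cases.

Peak coordinates are reported as 1-based voxel indices (the R convention;
stated in the report header). Phantoms share a grid by construction, so no
template registration or anatomical labelling is attempted.

## Numerical choices and degenerate inputs

- Zero-variance voxels are dropped from masks with warnings at every stage
  that would otherwise divide by zero.
- Identical-group baseline data return t = 0, p = 1 explicitly (the Welch
  statistic is 0/0 there).
- All-equal ANOVA cells return F = 0 for every effect via relative
  sums-of-squares guards.
- Eigenvalue ties (exactly anti-correlated voxel families) make the
  dominant eigenvector non-unique; both ECM routes stay nonnegative and
  agree on the eigenvalue, and the fast route deterministically returns the
  symmetric (uniform-start) solution.
- The Huynh–Feldt epsilon is clamped at 1 for reporting.

## Problem sizes used in the shipped verification

The test-suite and acceptance script exercise the pipeline at sizes chosen
to keep a full verification run on a single CPU comfortable: ECM oracle
agreement on twenty 150–500-voxel phantoms; lag recovery over 1000 noisy
trials; t-test size over 1000 null replicates; cluster-calibration over 200
null phantoms (16³ grid, 6 subjects/group, 100 volumes); end-to-end
planted-effect recovery at the documented phantom defaults (24³, 200
volumes, 10 subjects/group) over 20 seeds in the tests and 10 in the
acceptance script. These sizes are the package's verification conditions;
the functions themselves accept arbitrary dimensions.

## Known limitations

- Phantoms have no hemodynamic response, physiological cycles, scanner
  drift-spike realism, or inter-subject anatomical variability; conclusions
  about real-data robustness require real data.
- The permutation cluster null pools cluster sizes across permutations
  rather than using the max-cluster distribution; it matches the spirit of
  cluster-level FDR but is not identical to SPM's RFT-based procedure.
- Motion correction, distortion correction and registration are out of
  scope; users applying the ECM and inference modules to real data must
  supply spatially normalized, motion-corrected inputs.
- EC comparisons assume maps share a grid and mask; no resampling is
  provided.
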