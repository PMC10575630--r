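---
title: "Models, detectors and synthetic study conditions in mesoframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, detectors and synthetic study conditions in mesoframe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoframe)
```

mesoframe re-implements, as tested and reusable code, the analysis chain of
a freely-moving miniscope study of the mesofrontal dopaminergic circuit:
Y-maze spontaneous alternation scoring, PCA/ICA extraction of neuronal
components from one-photon calcium movies, derivative-based event
detection, position-binned ensemble and alternation-selectivity analysis,
Laplacian/Hessian quantification of dopaminergic boutons and axons, and the
accompanying statistics. This vignette documents the models, the tunable
parameters, the synthetic data that stand in for animal data, and the
numerical choices a maintainer would want to know about.

## Behavior: spontaneous alternation and trials

A three-arm Y-maze (arms 45 cm x 8 cm at 120 degrees) is explored
spontaneously. Entries are recorded as a letter sequence; the alternation
percentage is

> alternating triplets / (total entries - 2) x 100,

where a triplet of three consecutive entries counts as alternating when its
three letters are distinct. With no immediate re-entries an animal choosing
uniformly between the two available arms alternates at exactly 50%, which
is the chance level `chance_level()` reproduces by simulation.

Manual scoring requires "all four paws" in an arm; a body-center track
cannot observe paws, so `detect_arm_entries()` registers an entry when the
body center passes 33% of the arm length, with hysteresis at 15% so a
lingering animal is not double-counted. These fractions are exposed as
arguments. On the package's noise-free synthetic trajectories this proxy
inverts the generator exactly; on real tracks the thresholds matter and
should be reported.

`segment_trials()` cuts the track into terminal-to-terminal trials and maps
each sample onto 20 equal along-path bins (start terminal = bin 1, end
terminal = bin 20, maze center on the bin 10|11 boundary). A trial is
alternating when its end arm completes a non-repeating triplet with the two
preceding entries; the first two entries have no such history, so their
trials carry `NA` and are excluded from selectivity contrasts but retained
for position maps — the scoring rules are silent here and this choice keeps
the most data without biasing the contrast.

## Synthetic study conditions

No animal data ship with the package, so every stage is exercised on
synthetic data with ground truth. The generator defaults define the study
conditions used throughout the tests:

* **Agent**: `p_alt` controls the probability of choosing the non-recent
  arm; 0.5 is random exploration, ~0.7 reproduces wild-type-like behavior
  (~67-70% alternation) and ~0.55 a mutant-like deficit. Sessions default
  to 30 entries, the scale of an 8-minute session.
* **Locomotion**: 10 cm/s along the arm axis with a 1 s terminal dwell,
  sampled at 30 Hz. Ten cm/s is a moderate spontaneous running speed; it
  also sets the dwell time per position bin (~0.45 s), which matters
  because the indicator decay (below) spreads activity across bins — at
  much higher speeds the 20-bin selectivity statistic cannot localize
  amplitude differences for a slow indicator, a genuine property of the
  method rather than of the implementation.
* **Calcium transients**: difference-of-exponentials kernel with
  `tau_rise = 0.18 s`, `tau_decay = 1.8 s`, unit peak — the fast-rising,
  slowly decaying GCaMP6s shape the event detector assumes. Each neuron
  fires one transient per trial; the onset leads its tuned bin by the
  kernel time-to-peak (~0.46 s) so fluorescence is maximal at the preferred
  position. Background transients occur at 2 events/min. Noise is additive
  white Gaussian; `noise_sd = 0.1` with unit amplitude (SNR 10) is the
  standard test condition. Trial-type selectivity acts multiplicatively on
  amplitude (`selective_gain`, default 2), matching the amplitude-difference
  statistic downstream.
* **Movies**: footprints are compact Gaussians (sigma 3 px) summed into a
  baseline of 100 counts; vessels are static multiplicative shadows. The
  renderer conserves flux, so per-pixel dF/F0 recovers the planted
  temporal structure exactly in the noise-free case.
* **Histology phantoms**: axons are smooth random curves (direction
  random-walk, SD 0.03 rad/px) rendered as Gaussian tubes of
  `psf_sigma = 0.5 um` at 0.65 um/px on 512 px sections; boutons are
  Poisson-placed Gaussian puncta on the centerline, 12 per 100 um by
  default (dopaminergic varicosity spacing is a few microns, so this is
  conservative), green-channel dominant with a faint axon bleed-through.
  Cohort studies use 3 sections x 4 axons (~4,000 um of axon) per animal;
  with fewer axons the per-animal density estimate is too noisy for a 16%
  group deficit to be detectable at n = 7/group, i.e. the sampling, not
  the detector, limits power.

What the generators do **not** emulate: motion artifacts, bleaching,
overlapping somata, photon (shot) noise statistics, anisotropic PSFs, and
tissue autofluorescence gradients. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under clean, known
conditions, not robustness to every artifact of real recordings.

## Movie processing and component extraction

`compute_dff()` uses the session mean of each pixel as F0 and masks
non-positive pixels. `downsample_movie()` is block-mean pooling (default
4x), dropping trailing partial blocks.

`pca_ica()` follows the classic one-photon recipe: the T x pixels dF/F0
matrix is reduced by a randomized partial SVD to `n_pcs` components
(rule of thumb: ~3x the expected cell count; singular values below 1e-7 of
the largest are dropped so a noise-free rank-k movie yields exactly k
components), then a joint spatiotemporal ICA rotation is found by a
fixed-point iteration maximizing skewness — calcium sources are sparse and
positively skewed, so skewness is the separating contrast. `mu` weights the
temporal against the spatial part of the objective (default 0.5, equal
weighting). The iteration uses symmetric decorrelation, tolerance 1e-6,
at most 500 iterations (non-convergence warns and returns the current
estimate — typical for pure-noise movies, whose components are then
rejected anyway). Spatial filters are unit-norm; temporal signals are
sign-flipped to nonnegative skewness. The decomposition is deterministic
given `seed`.

Component selection implements two rules: temporal skewness below 1 rejects
a component (noise and blood-flow artifacts are near-symmetric, somatic
calcium is not), and a spatial filter whose top-5% pixels overlap a vessel
mask by more than 30% is rejected. The original procedure used human
inspection for the vessel rule; the automated criterion (vessel mask =
pixels below the 5th percentile of F0, `overlap_max = 0.3`) makes the stage
testable and is exposed in the arguments. Traces are extracted as
mean(soma) - median(annulus) per frame, the "doughnut" background
subtraction; the soma mask is the filter above 30% of its peak (a
peak-relative threshold is robust to image size, where a global quantile is
not), and the annulus spans 2-8 px outside the soma boundary, excluding
other somas, falling back to the global background median with a warning
if empty.

## Event detection

The rising phase of a calcium event is found from the first derivative of
dF/F0, computed as the least-squares slope in a centered 200 ms window
(6 frames at 30 Hz) — noise-robust, unlike a two-point difference. A
candidate is a maximal run of positive derivative containing at least one
sample above 5 baseline-SDs of the derivative; the event is kept when the
dF/F0 peak within the run exceeds the trace median by 3 baseline-SDs. The
event spans the run; its magnitude is dF/F0(end) - dF/F0(start).

Two readings of "5 SD of baseline fluctuation" are possible; the package
applies it to the derivative's own baseline because the quantity being
gated is a derivative, which makes both thresholds dimensionally
consistent. Baselines are robust (MAD x 1.4826) so transients do not
inflate their own threshold; consequently all thresholds are invariant to
adding a constant and equivariant under positive rescaling. A constant
trace has zero baseline scale and, having no positive-derivative run,
yields no events; noise-free transients remain detectable because the
thresholds degrade gracefully to zero. At SNR 10 the windowed slope of a
unit-amplitude transient (~4 /s) sits close to five derivative-SDs
(~3.6 /s), so sensitivity at that SNR is a genuine operating point of the
published thresholds, about 96-97% with perfect precision in the package's
calibration tests.

## Ensemble analysis

Activity is averaged per trial per position bin, then across trials (bins
unvisited in a trial are skipped for that trial); the per-neuron peak bin
is the argmax with ties broken toward bin 1 and flagged. Maps use raw
dF/F0, not event rasters. The proportion of neurons peaking at each
position gets a seeded percentile-bootstrap CI over neurons (2,000
resamples).

The "just before the maze center" window is fixed at bins 8-10 on the
1..20 start-to-end axis; nothing in the scoring rules pins this down, so
it is an explicit argument everywhere it is used. Group contrasts (peak
proportion in the window; proportion of neurons selective in the window)
are Pearson chi-square tests without continuity correction, appropriate
for the ~500-1,300 pooled cells per group these analyses see.

A neuron is alternation-selective at a position when its
alternating-minus-non-alternating activity difference there exceeds the
mean of the differences at all other positions by more than twice their
SD, a one-sided criterion ("higher than"); neurons with fewer than 3
trials of either type are not assessable. Note a structural property: the
SD is estimated from the 19 other bins, so under an exactly Gaussian null
the per-bin flag rate is slightly above the idealized one-sided 2-SD tail
(t-distribution inflation, partly offset by the indicator-induced
correlation between neighboring bins; simulations in the acceptance suite
measure ~2.4% against the 2.275% ideal). Users comparing groups are
unaffected — both groups share the inflation — but absolute selective
proportions should be read with this in mind.

Stimulation time courses use F0 = mean of the first 15 s, dF/F =
(Ft - F0)/F0, and summarize the response as the peak dF/F between 20 and
40 s (stimulus at 20 s). Overall spontaneous activity is summarized by the
SD of the trace, and treatment effects as (SD2 - SD1)/SD1.

## Histology quantification

Boutons: Laplacian-of-Gaussian response at 0.5 um scale, local maxima
above the robust background (median + 5 x MAD-SD of the response within
the ROI), minimum separation 2 sigma, sub-pixel quadratic refinement.
Cells: the same detector at 6 um scale and 2 SD. Axons: ridge strength is
the negative smaller Hessian eigenvalue at 0.75 um scale, thresholded at
2 SD above background; the mask is cleaned of connected components smaller
than 10 px (suprathreshold speckle — at 2 SD, 2.3% of pure-noise pixels
pass by construction), boundary-smoothed by a 3x3 majority vote (a ragged
threshold boundary makes the skeleton zig-zag and inflates length), thinned
to one pixel and pruned of spurs under 3 px. Length sums 8-neighbor steps
(1 or sqrt(2) pixels). Filter scales are arguments; the defaults match
~1 um boutons, ~1 um axons and ~12 um somata at 0.65 um/px.

Thinning is parallel Zhang-Suen followed by a sequential simple-point
cleanup in compiled code: the parallel scheme alone leaves two-pixel
diagonal staircases on noisy masks (a known fixed point), which double
apparent length; the cleanup deletes only pixels whose removal preserves
local 8-connectivity and that are not endpoints. With these steps a
500 um phantom tube is measured within ~1% at any orientation; border
bands where finite-difference filters see the image edge are excluded
from detection and background estimation.

Per animal, counts and lengths are summed across sections before ratios
(bouton density per 100 um of axon; axon length per labeled midbrain
cell), then optionally expressed as percent of the control-group mean —
summing before dividing matches the "total length / total count"
normalization chain. Bouton detection runs on the green channel
independently of the axon mask; at 5 SD over a whole blank section a
handful of >5-sigma noise maxima is expected by Gaussian tail arithmetic,
which is why quantification is restricted to a drawn ROI, as the original
procedure restricted it to the M2 region.

## Statistics

Two-tailed t tests come in a raw-sample form and a summary-statistic form
(mean, SEM, n per group) that reconstructs printed test statistics; the
default flavor is Student (pooled variance), consistent with the degrees
of freedom such analyses print, with Welch as an option. Chi-square is
Pearson without continuity correction. The stimulation ANOVA is a mixed
two-way design (between: group, within: time) whose group main effect is
tested against the between-subject stratum, giving F(1, n_a + n_b - 2).
Normality is Shapiro-Wilk. No multiple-testing correction is applied by
default, matching the source analyses. `build_report()` bundles results
with every configuration value and seed used, and round-trips through
JSON.

## Problem sizes used in the test suite

The suite runs entirely on synthetic data at sizes chosen to exercise each
method at its operating point: extraction recovery on a 64 x 64 x 3,000
movie with three planted sources; event calibration on 30 ten-minute
traces; chance-level alternation on 10,000 sessions of 30 entries;
selectivity calibration on ~1,000 pooled neurons across 8 sessions;
histology on 512-800 px phantoms, with ten 14-animal cohorts for the
group-deficit recovery; end-to-end group contrasts on ~500 cells per
group. A full run takes a few minutes on a single core.

## Known limitations

* The extraction stage implements the skewness-ICA recipe, not modern
  constrained NMF approaches; heavily overlapping cells are out of scope.
* Entry detection and trial segmentation assume a body-center track in
  maze coordinates with the center at the origin.
* The selectivity statistic's null calibration is slightly anticonservative
  in absolute terms (see above).
* Bouton counts under-count at high densities because puncta closer than
  about two PSF sigmas are physically unresolvable and merge; group ratios
  are much less affected than absolute counts.
* Histology operates on 2-D (maximum-projected) images; no 3-D
  skeletonization.
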