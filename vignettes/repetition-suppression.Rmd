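---
title: "Tonotopic parcellation and repetition suppression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tonotopic parcellation and repetition suppression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonorep)
```

# The scientific problem

Early-stage auditory cortex on the supratemporal plane contains two
mirror-symmetric primary fields: A1, whose preferred frequency falls from
high to low along the posterior-to-anterior axis, and R, which rises from
low back to high, the two sharing a low-frequency ridge. A frequency
selective but not clearly tonotopic belt surrounds this core. Whether these
small fields encode the *meaning* of environmental sounds — not just their
acoustics — can be probed with repetition suppression: blocks of eight
different exemplars of one sound source (REP) are contrasted with blocks of
eight different sources (CTRL). If a region's neural population codes the
source identity, its sustained BOLD response adapts under REP and sits
below the CTRL response during the plateau of the block response.

`tonorep` implements this full analysis on synthetic data with known ground
truth: a generator for tonotopic sheets, travelling-wave runs, block-design
repetition runs and sound pools; travelling-wave mapping by lagged
cross-correlation; gradient-reversal parcellation into the ten canonical
areas (A1, R, M1–M4, L1–L4); iterative acoustic matching of stimulus sets;
and slope-based time-course segmentation with per-frame statistics.

# The travelling-wave model

A tonotopy run presents 14 pure tones (88–8000 Hz in half-octave steps,
`tone_frequencies()`) in an ordered 2-s-per-step progression followed by a
4-s pause — a 32-s cycle repeated 15 times (240 frames at TR 2 s). A voxel
tuned to one tone responds once per cycle, at a cycle position that encodes
its best frequency. `best_frequency_map()` correlates each voxel's series
against a canonical single-step response (`build_reference_cycle()`:
haemodynamic model convolved with one 2-s step, wrapped to the cycle)
shifted by all 16 whole-frame lags; the arg-max lag (ties broken to the
earliest lag, deterministically) is the voxel's response delay in stimulus
time, and the tone presented at that position is its best frequency.

Two conventions deserve mention:

* **Delay handling.** Because the reference already contains the assumed
  haemodynamic model, no explicit delay subtraction is needed. If the true
  response delay differs from the assumed one, the ascending run's estimate
  shifts up the ladder and the descending run's shifts down by the same
  number of steps; `combine_directions()` averages the two on the
  log-frequency scale (the ladder is multiplicative) and snaps to the
  nearest step, cancelling the bias exactly for interior ladder steps. This
  is the computational reason for acquiring both directions. At the two
  ladder ends the estimate saturates (there is no step beyond 8000 or below
  88 Hz), so a residual half-step error can survive there; the package's
  tests therefore assert exact cancellation on interior steps.
* **Pause lags.** A lag falling in the silent pause corresponds to no
  presented tone; it is wrapped to the nearest presented step in circular
  time. Constant voxels have undefined correlation and are excluded with
  reason `"constant"`; voxels whose two direction estimates disagree by
  more than 2 steps are flagged `"unreliable"` and dropped from the mask.

Thresholding uses r > 0.13, which at n = 240 frames corresponds to
p ≤ 0.05 (uncorrected) under the exact t transform implemented in
`r_to_p()`. Note that the *null* rate of exceeding 0.13 is higher than 0.05
for the mapped r, which is a maximum over 16 lags; the threshold is a
practical mask level, not a calibrated test, and the package's null
simulations quantify the actual exceedance rate.

# Gradient-reversal parcellation

The delineation drawn by hand in real studies is automated here as a set of
deterministic rules operating on the masked best-frequency map:

1. **Patch.** The largest 6-connected suprathreshold component — the
   analogue of outlining one contiguous patch of interest and the step that
   protects everything downstream from isolated noise voxels.
2. **Core columns.** For every medial–lateral position, the log-frequency
   profile along the posterior–anterior axis (pooled over a 3-column
   window) is scanned for its strongest reversal: the interior position
   maximising the smaller of the descending and ascending monotone spans
   around it. A column belongs to the core when that score exceeds half the
   ladder's range (3.25 octaves of 6.5). The surround is frequency
   selective with at most ±1 step of local scatter, so it can never meet
   this criterion; the core spans the full ladder and always does. The
   core is the longest contiguous run of qualifying columns.
3. **Borders.** The profile pooled across core columns (rows supported by
   at least half the core width) gives the low-frequency ridge (A1/R
   border) and, on each side of it, the outer high-frequency maxima
   (posterior and anterior borders). A1 is the posterior, high-to-low
   gradient; R the anterior one. In the noiseless limit these rules
   reproduce the generating geometry exactly.
4. **Surround subdivision.** The three border lines are extended across the
   patch, cutting it into four posterior-to-anterior sectors; each sector
   splits into a medial and a lateral part at the core's edges, giving
   M1–M4 and L1–L4 (numbered posterior to anterior) plus A1 and R — ten
   labels that partition the patch by construction. The strip directly
   posterior/anterior of the core carries no core edge; it is split at the
   core midline, with ties going to the medial label. This last rule is a
   declared convention: nothing in the drawing procedure it automates
   determines the split, so the package fixes one deterministically.

# The repetition-suppression generator

CTRL blocks drive a 16-s neural boxcar; REP blocks drive the same boxcar
scaled by a region-specific factor after an initial unsuppressed lead
(default 2 s, i.e. the first, unadapted stimulus). This is the simplest
mechanism that produces both a lower sustained response and an earlier
saturation of the REP time course. The default profile suppresses A1, R and
M1–M4 at factor 0.8 and leaves L1–L4 untouched; the factor is a free
parameter of `suppression_profile()` because published block designs do not
pin down per-area effect sizes numerically — the default is calibrated to
give a clearly detectable but not saturating effect at the cohort size
simulated here.

**Haemodynamic model.** The double gamma of `hrf_model()` is parameterised
by the peak (mode) delay and dispersion of each lobe and scaled so that a
sustained block saturates at 1. The defaults — positive lobe peaking at 4 s
with 0.75 s dispersion, undershoot at 14 s with ratio 0.03 — describe a
compact early-auditory response whose block response rises between ~2 and
6 s after onset, is flat from 6 to 18 s, and returns to baseline between 18
and 22 s when sampled at TR 2 s. A slower or more dispersed positive lobe
(e.g. peak 5 s with dispersion ≥ 1 s) smears the saturation past 8 s, and a
canonical-sized undershoot (ratio 1/6) tilts the plateau by ~0.03 units per
frame — both incompatible with the flat-plateau dynamics this generator is
meant to emulate; hence the compact defaults. Subject-level variability is
modelled by `sample_subject_hrfs()`: amplitude ~ N(1, 0.1), peak delay
jittered by 0.2 s, undershoot ratio folded-normal around the base value.

**Noise model.** Two additive Gaussian components: voxel-wise white noise
(SD 1.0 in units of the plateau amplitude, i.e. an SNR of ~1 per voxel and
frame) and a *global* per-frame term (SD 0.3) shared by all voxels.
The global term matters: purely voxel-wise noise shrinks as
1/sqrt(voxels × blocks) under ROI averaging, leaving per-subject standard
errors so small that even trivial systematic slopes (the undershoot, the
REP onset transient) become "significant" — behaviour never seen in real
ROI analyses, where spatially coherent physiological fluctuations set a
noise floor. The same two-component model is used for tonotopy runs, where it leaves
responsive voxels comfortably above the r = 0.13 mask threshold, as is
typical of travelling-wave mapping at high field.

# Time-course extraction and statistics

`extract_block_timecourses()` follows the classic block pipeline: spatial
mean over each ROI's voxels; per block, the 15-frame window from onset;
baseline correction against the mean of the two frames preceding the onset
(the cleanest window, since the previous block's response has decayed by
then; the first block, which has no preceding frames, uses the run's first
two frames); conversion to percent signal change; averaging across
same-condition blocks and runs; and subtraction of the first time point, so
every time course starts at 0. Blocks extending past the run end are
dropped with a warning.

**Segmentation** (`segment_phases()`): consecutive frames are subtracted
pairwise and each of the 14 transitions is tested against zero with a
paired t-test across subjects (two-sided, α = 0.05, uncorrected).
Significant positive → rise, significant negative → decay, otherwise
plateau. Phases require at least two consecutive agreeing transitions;
singleton labels are absorbed — an interior singleton between two runs of
the same label joins them, any other non-plateau singleton falls back to
plateau, and edge plateau singletons are left alone (so no rise or decay is
ever fabricated at the block boundaries). "Positive/negative significance"
is implemented as the significance of the slope test combined with the
slope's sign; a p-value itself cannot be negative, and this reading is the
only coherent one. With fewer than 3 subjects the t-test is undefined or
degenerate, so the function refuses to run.

Under the default generator with 9 subjects × 2 runs, the segmentation
recovers rise ≈ 2–6 s, plateau 6–18 s, decay 18–22 s (the acceptance
script recomputes the two onsets from scratch). Across replications the
occasional miss is the α-level false-positive rate of the slope test
itself — a spuriously significant plateau transition adjacent to the decay
run cannot be absorbed — and is irreducible at p < 0.05 without changing
the paradigm.

**Contrast** (`contrast_conditions()`): per-frame paired t-tests REP vs
CTRL; the repetition-effect verdict requires at least two consecutive
significant CTRL > REP frames *among the frames inside the plateau window*.
A significant run is allowed to extend into the decay — the REP response
returns to baseline earlier, so the difference often outlasts the plateau —
and counts through its in-plateau portion. Frames where both conditions are
numerically identical give an undefined t and are assigned p = 1.

**Plateau ratio** (`plateau_ratio()`): the suppression factor is estimated
as the ratio of group-mean REP to group-mean CTRL signal over 8–18 s. The
window excludes the first plateau frame, which still carries the
unsuppressed 2-s onset transient of REP blocks; the ratio of group means is
used because the mean of per-subject ratios is biased upward by the noisy
per-subject denominators. So measured, the estimate is unbiased to within
well under 0.03 across factors 1.0/0.9/0.8/0.7 at the default SNR.

**ANOVA** (`anova_2x2_timepoint()`): per frame, a two-way repeated-measures
ANOVA with hemisphere and condition as within-subject factors, implemented
as the closed-form sums-of-squares decomposition with each effect tested
against its own effect-by-subject error term (the same nine subjects
contribute all four cells, so a repeated-measures model is the only
defensible choice). Effects with zero sum of squares report F = 0, p = 1.
The decomposition is verified in the tests against `stats::aov` with the
corresponding `Error()` strata to 6 decimals, and against the F = t²
identity when one factor is inert.

**Extrema** (`extrema_stats()`): per subject and condition, the maximum,
minimum and amplitude (max − min) of the 15-frame time course, compared
between conditions with paired t-tests.

**Localizer GLM** (`glm_sound_vs_rest()`): a single-regressor linear model
per voxel (assumed haemodynamic model convolved with the pooled REP + CTRL
stimulation boxcar, plus intercept), with optional Bonferroni thresholding
across in-mask voxels.

# Stimulus generation and acoustic matching

Synthetic 500-ms sounds at 44.1 kHz are band-filtered Gaussian noise with a
random log-frequency centre (default 800 Hz ± 0.4 octaves, 1-octave band),
multiplied by a random smooth envelope modulation, shaped by 50-ms linear
rise/fall ramps and peak-normalised. They reproduce the two statistics the
matching procedure controls — the temporal envelope and the amplitude
spectrum — with realistic within-class variability, and nothing else about
natural sounds (no harmonic structure, no semantics).

`compare_sets()` tests the two sets at every envelope time point (default
500 points, 1-ms resolution — the natural reading of "each time point" for
a 500-ms stimulus, configurable) and every spectral bin (11025 one-sided
DFT bins at 2-Hz spacing) with two-sided pooled-variance Student t-tests,
deliberately *uncorrected*: when the test is used as a matching criterion,
missing a real difference is the costly error, so the per-point power is
kept maximal. `select_matched_sets()` draws random disjoint REP/CTRL sets
(stratified by semantic category when tags are present), accepts the first
draw with under 1% significant points, and reports an explicit failure with
the best draw found when the cap (default 1000 iterations) is exhausted —
never a silent unmatched set. `compare_mean_spectra()` runs the per-bin
spectrum comparison alone and reports raw and Bonferroni-corrected counts.

On a single-class 300-sound pool random draws meet the 1% rule often
enough that acceptance takes a handful of iterations; the 1000-iteration
cap matters for heterogeneous pools (the band-disjoint construction in the
tests shows the failure path).

# Problem sizes, tolerances, degenerate inputs

* Default sheet: 32 × 44 × 1 voxels (1.5 mm), core 12 × 16, surround 8 —
  ~900 patch voxels, A1 and R 96 voxels each. Tests use a 16 × 22 sheet
  where only the statistics, not the geometry, are under test.
* Monte-Carlo sizes in the test suite: 20 seeds for the partition
  invariant, 200 cohorts for type-I calibration, 30/60 cohorts for
  power/false-positive rates of the verdict, 25 cohorts × 4 factors for
  ratio recovery (standard error of the recovered mean ≈ 0.007, against a
  0.03 bias bound). These sizes keep the default suite in the minutes
  range while leaving the checks far from their decision boundaries.
* Ties: equal correlation at several lags → earliest lag; frequency snap
  ties → lower step; medial/lateral split ties → medial. All deterministic.
* Degenerate inputs: constant voxels, all-rest designs, unpaired subjects,
  incomplete ANOVA cells, < 3 subjects, pools too small to split, and
  non-4-D volumes all raise explicit errors; zero-variance comparison
  points get p = 1.

# What passing tests do and do not show

The generator emulates the *structure* of the paradigm — geometry of the
double gradient, block timing, suppression dynamics, ROI-level noise — not
real cortical anatomy (no folding, no Heschl's gyrus variants, no
myeloarchitecture), not scanner noise spectra, and not the semantics of
natural sounds. Passing the suite demonstrates that the analysis code
implements its stated rules exactly and recovers known ground truth under
realistic noise; it cannot certify how the pipeline behaves on real brains,
where the manual steps it automates (patch outlining, border drawing)
involve anatomical judgement the rules do not capture.

# Known limitations

* The parcellation assumes one dominant reversal pair; a third gradient
  (an RT-like field) would be folded into the surround, with a warning.
* Ladder-edge frequencies saturate in the direction-combination step.
* The medial/lateral split of the outer sectors is a convention, not an
  inference of the drawing procedure it replaces.
* The per-frame statistics treat frames independently (as in the original
  procedure); no temporal autocorrelation model is fitted.
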