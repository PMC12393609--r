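---
title: "Methods: from tail movies and calcium traces to brain-wide group differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tail movies and calcium traces to brain-wide group differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinesia)
```

## What the pipeline does

`kinesia` implements the analysis chain used to relate chemogenetic
ablation of catecholaminergic (tyrosine-hydroxylase-expressing) neurons
in larval zebrafish to its two behavioral faces — impaired free
swimming, and paradoxically *increased* struggling under head-fixed
two-photon imaging — and to the brain-wide neural activity changes that
accompany them. The chain has six stages, each a module of the package:

1. open-field tracking and locomotor metrics with an impairment
   classifier (`detect_arenas`, `track_larva`, `compute_metrics`,
   `classify_impairment`);
2. tail kinematics: skeleton to a single baseline-corrected tail angle
   (`segment_angles`, `summary_angle`, `fill_nans`, `remove_baseline`,
   `resample_to_imaging`);
3. tail-swing event detection and classification against a noise-floor
   unit (`noise_floor`, `detect_events`, `merge_events`,
   `classify_event`);
4. calcium-trace curation, normalization, constrained AR1 spike
   deconvolution and firing-rate estimation (`curate_rois`,
   `normalize_and_baseline`, `deconvolve_ar1`, `firing_rate`);
5. cube-overlap assignment of neurons to atlas masks and two-group
   statistics with a Relevance ranking (`neuron_cube`,
   `assign_regions`, `build_heatmaps`, `voxelwise_test`,
   `map_to_masks`, `region_test`);
6. motor-associated clustering with the tail trace and region-pair
   connectivity (`motor_partition`, `connectivity`).

No recordings ship with the package. A synthetic-data module generates
every input with planted ground truth, so the full chain is testable:
`generate_toy_atlas`, `generate_calcium_cohort`, `generate_tail_trace`,
`render_freeswim_movie`, `render_multiwell_background`.

## Free-swimming behavior

Wells are found on a background image (maximum projection of the first
and last minute of video) by Gaussian smoothing and thresholding at 1.2
times Otsu's threshold; the bright connected components must match the
configured well count or the stage fails loudly. The larva itself is
the dark eye cluster of an otherwise transparent animal: per frame the
tracker keeps the largest blob at least 10 intensity units darker than
the background that survives a morphological opening and a size gate.
Missing frames are filled from the nearest valid neighbor — not
interpolated, to avoid inventing motion — and more than 20% missing
flags the trajectory.

Eight metrics are computed at a 40-Hz analysis rate: total distance,
RMS speed, percent of arena explored (1.75-mm occupancy bins, 20 × 20
per 35-mm well), bout rate, inter-bout interval, bout amplitude,
percent time actively swimming, and thigmotaxis (percent time within
6.75 mm of a wall, 1.5 × the 4.5-mm body length). The source protocol
never defines a "bout"; here a bout is ≥ 3 consecutive analysis frames
above 2 mm/s, separated by ≥ 100 ms below threshold, and the active-
swimming percentage is derived from the same definition. All of these
are config-exposed. A larva is *impaired* iff it explores strictly less
than 35% of its arena — exploration being the most ablation-sensitive
of the eight metrics.

Per-group outlier exclusion uses the scaled-MAD rule (exclude iff
|v − median| > 3 × 1.4826 × MAD, strict comparison). The strict
comparison reproduces the standard MATLAB `isoutlier` semantics at
MAD = 0: an all-equal list excludes nothing, while a majority-constant
list excludes everything off the median.

## Tail kinematics

The tail skeleton (ordered base-to-tip points per frame) is split into
8 segments **by point count**, the first `n mod 8` segments absorbing
the remainder. Each segment gets a cubic fit, a line is fit to the
evaluated cubic, and the line's angle to the x-axis is the segment
angle. The frame's summary angle connects the user-selected base point
to the mean position of the points in segments 4–7. Sign convention
(the source never fixes one): head toward −x, image y downward
(bottom-view camera), positive = deflection toward the animal's right;
mirroring the skeleton negates every angle and swaps left/right labels
downstream.

NAs (frames without a detectable tail) take their nearest valid
neighbor, earlier sample on ties. The resting-tail drift is removed by
a 1-minute bidirectional windowed **median** (the statistic is a
package choice; a median is robust while events occupy < 50% of any
window). For speed at 200 Hz the median is evaluated on a coarse grid
(≤ 1 s) and interpolated; each truncated edge window is anchored at its
midpoint and the baseline extended linearly past the outermost anchors,
which makes removal of linear drift exact including at the trace edges.
The operator is exactly idempotent on linear drift; on sinusoidal drift
a curvature bias of a few percent of the drift amplitude remains (it
shrinks on a second pass), which the tests assert explicitly.

Resampling to the 1-Hz imaging rate deliberately avoids interpolation,
which flattens tail beats briefer than the imaging frame: each 1-s bin
drops samples above the within-bin 90th percentile of |angle| (linear
interpolation between order statistics, `type = 7`) and reports the
maximum remaining |angle| with its sign. Single-sample bins pass
through; a bin that trimming would empty keeps all its samples.

## Tail-swing events

The **noise floor** (NF) is the RMS of the whole baseline-corrected
trace, computed once per recording; every threshold is a multiple of
it. An event must contain a peak with |angle| > 3 × NF and prominence
> NF; its extent runs between the 1 × NF crossings around the peak, so
events never overlap, and events separated by < 2 s merge
(transitively; a gap of exactly 2 s does not merge). Classification is
a cascade: *struggle* iff both signed extremes exceed 10 × NF (about
45° at a typical 4.5° noise floor); otherwise the sums of samples with
|angle| > 3 × NF decide — a 20-fold dominance of one side is a *flip*
on that side (an empty opposite sum counts as infinite dominance);
everything else is a *swim*.

The synthetic trace generator specifies event amplitudes in units of
the **nominal** noise floor (the noise s.d.). Two calibration facts
matter and are deliberate design choices:

* Noise is a normal truncated at 2.5 s.d. Real tail-angle jitter of a
  resting tail is bounded; unbounded Gaussian noise at 200 Hz over 24
  minutes would cross 3 × NF ~100 times per trace by chance alone and
  make a 95% planted-event recovery unmeasurable.
* The classifier thresholds apply to the *realized* noise floor, which
  includes event samples. The default plan keeps the event duty cycle
  under ~5% so realized/nominal stays ≈ 1.2, and the default amplitudes
  (swim 7×, off-side 5.5×, flip 9×, struggle 18×) sit safely on the
  intended side of every threshold after that inflation.

## Calcium traces and firing rates

Candidate ROIs from an upstream source extractor are curated: size
bounds, an activity gate (peak excursion above the median, in units of
the difference-based noise estimate `mad(diff(y))/sqrt(2)`; pure noise
peaks near 3, the gate is 5), and a merge rule for wrongly split cells
(centroid distance < 8 μm, trace Pearson r > 0.9, contiguous
footprints; merged traces are footprint-weighted means).

Each trace is min-max normalized to [0, 1] and a dynamic baseline over
a 2-minute centered window is subtracted. The baseline statistic is a
running 8th percentile with *value-position anchoring*: each window
contributes its quantile value anchored at the median time of the
samples near that value. For a rising drift those samples sit at the
window's left end, for a falling drift at the right, and around an
extremum at both ends with a central median — so linear drift of either
sign is removed exactly and slow sinusoidal drift leaves only a
curvature-limited residual (< 2% of the transient amplitude in the
tests). Per-neuron dF/F is summed over time and z-scored across the
neurons of each larva (population denominator, n; the sample
alternative is available by option). The z-reference is per-larva, not
pooled, consistent with the per-larva normalization used before
clustering.

Spikes are inferred by constrained nonnegative AR1 deconvolution
(`c_t = γ c_{t−1} + s_t`, `s_t ≥ 0`): a pool-adjacent-violators pass
gives the exact l1-penalized solution at a fixed penalty, and the
penalty is raised by bisection until the residual meets the noise
constraint ‖y − c‖ ≤ σ√T. With σ = 0 the solution is exact and planted
spikes return bit-for-bit. γ can be fixed by config (the indicator's
decay at the imaging rate, 0.9 by default in the pipeline) or estimated
per neuron from the lag-2/lag-1 autocovariance ratio clipped to
[0.5, 0.99]; the estimator is slightly biased low (~0.89 for a true
0.9 at 1445 frames), which is why fixing γ from indicator kinetics is
the default where the rate matters.

The firing rate divides the number of spike *peaks* (local maxima of
the deconvolved amplitudes above 0.5 × MAD of the nonzero amplitudes)
by the recording duration (1445 s for the standard 24-minute, 1-Hz
protocol). The gate multiplier is a package convention: under the noise
constraint genuine transients shrink to amplitudes an order of
magnitude above the spurious noise-induced events, and 0.5 × MAD of the
mixed nonzero set falls inside that gap (a 2 × MAD gate lands above the
genuine amplitudes and undercounts by ~85% on simulated traces). With
this convention, mean rates at SNR 5 are recovered within ~3% with γ
fixed.

## Atlas mapping

Neuron centroids live on a reference grid of 1 × 1 × 2 μm voxels
(full scale 500 × 1000 × 200 voxels). After a +5 μm z-offset (half the
10-μm volumetric step, compensating the steadily moving objective),
each neuron becomes an axis-aligned 5 × 5 × 6 μm cube — the centroid
voxel ± 2 in x and y and ± 1 in z, i.e. exactly 75 voxels in the
interior, clipped at faces (50 at a z-face, 45 at an x/y-face). A
neuron joins every mask its cube overlaps in ≥ 10 voxels; overlapping
masks make this many-to-many by design. Per-region tables hold the
active-neuron count, summed z-scored cumulative dF/F and mean firing
rate, with empty regions flagged rather than zero-filled.

Ablation efficiency in the marker channel is quantified per composite
mask as 100 (a − b)/a, where a and b are suprathreshold voxel counts in
0–1 normalized control and treated stacks. The counting threshold
starts at 0.2 and moves on a 0.05 grid in [0.1, 0.5], choosing the
threshold whose per-larva counts have the fewest 3-scaled-MAD outliers,
ties resolved toward 0.2 — the iterative schedule itself is a declared
convention, config-overridable.

## Group comparison and Relevance

Per-larva heatmaps at 12 × 12 × 12 μm accumulate each active neuron's
metrics into the voxel containing its centroid (`floor(μm/12)`; grid
shape `ceiling(extent/12)` — the package documents its own shape rule
rather than forcing any particular printed z-extent). Count and dF/F
voxels default to 0; rate voxels with no neurons are *missing* and
excluded from testing. Each touched voxel gets a two-sided Wilcoxon
rank-sum test across larvae (exact when both n ≤ 10 without ties,
normal approximation with tie correction otherwise); the group
difference (deficient − control) is masked to voxels with p < 0.05. No
multiple-testing correction is applied at voxel or region level,
matching the p < 0.05 convention of the source analysis; an FDR mode
exists but is off by default.

Masks are downsampled to the heatmap grid (a coarse voxel belongs if
any fine member voxel does) and each mask receives, per metric and
direction, the percentage of significantly altered voxels and the sum
of masked differences. The **Relevance** score is the sum of the
absolute values of the six directional sums (three metrics × two
directions) and ranks the masks. Region-level tests compare per-larva
region statistics with the rank-sum test and optionally a permutation
test on the mean difference (exact enumeration when feasible, seeded
Monte-Carlo otherwise), reporting the *larger* of the two p-values and
the percent change of the deficient mean against the control mean.

## Motor clustering and connectivity

Neuron traces are z-scored over time, rescaled to [0, 1], and the
normalized 1-Hz tail trace is appended as the last row. One
hierarchical tree is built with distance 1 − Spearman ρ (average
ranks for ties) and average linkage. Starting at t = 3 clusters, the
cut grows by one cluster per iteration while tracking the cluster
containing the tail row; the first time that cluster shrinks by more
than 20% relative to the previous cut, iteration stops and the
previous assignment wins. Neurons sharing the tail's cluster are
motor-associated. Two conventions the source leaves open are settled
(and config-exposed): the cluster count increments by one, and the 20%
reference is the previous iteration's size, not the initial one. A
degenerate tree (all rows rank-identical) returns a single all-motor
cluster. Constant neuron rows carry no rank information and are placed
at maximal distance; a constant tail trace is an error.

Connectivity between two regions is the percentage of cross-region
neuron pairs whose Spearman correlation exceeds 0.8 (within-region
pairs excluded); it is symmetric by construction on unordered pairs.

## The synthetic cohort and what passing tests do (and do not) show

`generate_calcium_cohort` inverts the inference model: active neurons
(fraction 0.6 in controls) fire Poisson spikes at 0.05 Hz, calcium
follows the AR1 recursion, and fluorescence adds a slow sinusoidal
drift (period ≥ 5 min — precisely what the 2-minute moving baseline
exists to remove) plus Gaussian noise (default SNR 5). Deficient larvae
scale the active fraction (+30%) and the rate (−25%) inside the
affected regions only. A light mode (`traces = FALSE`) draws the
per-neuron spike counts from the identical distribution without
materializing traces, for statistical-power runs.

Problem sizes are scaled to desk hardware and stated here as the
package's own choices: power runs use 10 + 10 larvae with 1000 neurons
each over a 10-region toy atlas (~100 neurons per region — far sparser
than the tens of thousands per real larva, but dense enough that the
planted +30%/−25% effects are detected with power ≥ 0.95 while ~40 per
region would put the effect at the edge of detectability);
deconvolution runs use 100 neurons at the real 1445-s duration; event
recovery uses 50 traces at the real 200 Hz × 24 min.

The generator emulates the *structure* of the real data, not its
nuisance: no motion artifacts, no bleaching nonlinearity, no neuropil
contamination, no optical PSF, no correlated population activity beyond
the planted motor coupling, and bounded (truncated) behavioral noise.
Passing tests therefore demonstrate that the analysis chain is
internally correct and recovers known truth under its own model
assumptions — not that those assumptions hold for any particular
recording.

## Numerical choices and degenerate inputs

* Quantiles interpolate linearly between order statistics (`type = 7`),
  config-exposed.
* Wilcoxon: exact iff both n ≤ 10 and tie-free; permutation p-values
  are exact by enumeration up to 20,000 splits, else seeded with
  p ≥ 1/(n_perm + 1).
* `fill_nans` errors on an all-NA trace; `detect_events` errors on a
  zero noise floor; `motor_partition` errors on a constant tail trace;
  empty candidate lists and zero-length trajectories error rather than
  return silently empty results.
* Deconvolution non-convergence (residual above 1.05 × target after
  bisection) flags the record; it never silently zeroes a trace.
* Pipeline stage seeds derive from the master seed by a stable hash of
  the stage name, so any stage can be rerun in isolation; two runs with
  one seed are checksum-identical.

## Known limitations

Skeletonization assumes a roughly head-left horizontal tail (per-x
medial axis), adequate for the rendered fixtures and blurred frames but
not for a tail curled past vertical. The iterative ablation-threshold
schedule and the bout definition are declared conventions where the
source is silent. The voxelwise tests treat voxels independently;
spatial correlation is not modeled. γ estimation from autocovariance
is biased low at short trace lengths — fix γ from indicator kinetics
when absolute rates matter.
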