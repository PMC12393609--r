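# kinesia

Behavior and whole-brain calcium-imaging analysis for larval zebrafish
catecholamine-ablation studies.

## The problem

Ablating tyrosine-hydroxylase-expressing (catecholaminergic, CA)
neurons in larval zebrafish produces severe free-swimming locomotor
deficits — yet the same larvae, head-restrained under a two-photon
microscope with the tail free, move *more* than controls, a
paradoxical-kinesia-like recovery under strong multimodal stimulation.
Linking the two observations requires a long analysis chain: open-field
tracking and an impairment classifier, tail kinematics and
swim/flip/struggle event classification, calcium-trace deconvolution
and firing-rate estimation, assignment of neurons to thousands of atlas
region masks, voxelwise and region-level two-group statistics, and
clustering of neural activity with the tail trace. `kinesia`
implements that chain as tested, reusable R functions, with a
synthetic-data module that generates every input with planted ground
truth so the whole pipeline runs and is verified without any recording.

## The core methods

* **Impairment classifier** — a larva is impaired iff it explores
  < 35% of its arena in 15 min; the thigmotaxis boundary is 6.75 mm
  (1.5 × the 4.5-mm body length).
* **Tail events** — with noise floor `NF = sqrt(mean(θ²))` of the
  baseline-corrected tail angle θ(t), an event needs a peak
  > 3 NF with prominence > NF; events < 2 s apart merge; *struggle* iff
  both signed extremes exceed 10 NF; else a 20-fold one-sided dominance
  of the angle sums (samples > 3 NF) is a *flip*; the rest are *swims*.
* **Spike inference** — constrained nonnegative AR1 deconvolution
  `c_t = γ c_{t−1} + s_t`, `s_t ≥ 0`, solved exactly by a
  pool-adjacent-violators pass with the l1 penalty raised until
  `‖y − c‖ ≤ σ√T`; firing rate = spike peaks / 1445 s.
* **Atlas mapping** — each neuron is a 5 × 5 × 6 μm cube (75 voxels on
  the 1 × 1 × 2 μm grid, after a +5 μm z-offset); ≥ 10 overlapping
  voxels assign it to a mask. Ablation loss per mask is
  `100 (a − b)/a` on thresholded marker volumes.
* **Group comparison** — per-voxel (12-μm grid) and per-region
  two-sided Wilcoxon rank-sum tests (optionally the larger of rank-sum
  and permutation p), and a **Relevance** score: the sum of absolute
  directional difference sums over three metrics × two directions.
* **Motor clustering** — average-linkage hierarchical clustering on
  1 − Spearman ρ with the tail trace appended; the cut grows from
  t = 3 until the tail cluster would shrink > 20% in one step; region
  connectivity = % of cross-region neuron pairs with ρ > 0.8.

## Worked example

```r
library(kinesia)

# plant four tail events, recover and classify them
plan <- tail_event_plan(c("swim", "struggle", "right_flip", "swim"))
gen  <- generate_tail_trace(plan, noise_sd = 1.5, frame_rate = 200,
                            duration_s = 60, seed = 1)
tr <- remove_baseline(fill_nans(gen$trace))
ev <- detect_tail_events(tr)
ev
#>   onset_s offset_s peak_deg prominence_deg       type
#> 1    5.15     5.46     11.9           11.9       swim
#> 2   17.69    18.11     28.8           28.8   struggle
#> 3   30.34    30.70     14.0           14.0 right_flip
#> 4   42.97    43.21     12.4           12.4       swim
attr(ev, "noise_floor")
#> [1] 2.06   # degrees: RMS of the corrected trace

# noiseless AR1 deconvolution is exact
s <- rep(0, 300); s[c(50, 120, 250)] <- 1
y <- as.numeric(stats::filter(s, 0.9, method = "recursive"))
fit <- deconvolve_ar1(y, gamma = 0.9, noise_sd = 0)
which(fit$spikes > 1e-8)
#> [1]  50 120 250
firing_rate(fit$spikes, 300)
#> [1] 0.01   # Hz: 3 peaks / 300 s
```

All four planted events come back with the right type and timing; the
noise floor (2.06°) exceeds the nominal 1.5° noise s.d. because the RMS
includes the event samples. The deconvolved spike train reproduces the
planted frames exactly, and the rate is peaks over duration.

## The analysis workflow

`analysis/` holds six numbered drivers that run the chain on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # atlas, cohort, tail traces
Rscript analysis/02_freeswim.R        # tracking + locomotor metrics
Rscript analysis/03_tail_events.R     # event recovery vs planted truth
Rscript analysis/04_calcium.R         # deconvolution + rate recovery
Rscript analysis/05_atlas_comparison.R # relevance + region tests
Rscript analysis/06_clustering.R      # motor partition + connectivity
```

Stage 5, for instance, plants +30% active neurons and −25% firing rate
in 3 of 10 toy-atlas regions and recovers exactly those three regions
as significant (rank-sum and permutation), with the affected regions
leading the Relevance ranking.

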