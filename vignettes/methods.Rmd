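---
title: "Model-based fMRI mappings: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based fMRI mappings: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmap)
```

`cogmap` builds and validates mappings from the modules of a cognitive
architecture (visual, aural, manual left/right, declarative memory, problem
state) to brain regions. This vignette explains the underlying models, the
parameters that matter, the numerical choices, and what the synthetic-data
validation does and does not establish.

## Demand functions and task simulations

A module's activity is a 0--1 *demand function*: 1 while the module is busy,
0 otherwise, represented as sorted, disjoint half-open intervals
`[onset, offset)` in seconds (`demand_trace()`). Modules run in parallel but
each is serial within itself, so overlapping intervals within one module are
a validity error, not a representation choice.

Two schedule-level task simulations generate traces. They reproduce trial
structure and timing, not production rules or subsymbolic activation — there
is no learning and no conflict resolution beyond resource queuing.

**Pyramid algebra.** A problem `base $ height` is solved by repeated
addition (`4 $ 3 = 4 + 3 + 2 = 9`). One of base/height/value is unknown:
the value by running the addition chain (`height − 1` additions), the height
by running the chain until the target is reached, the base by guess-and-check
(evaluate a guess; report it, or its successor if the result fell short, or
its predecessor if it overshot). We note a subtlety in the height
convention: the chain for height *h* contains *h − 1* additions, which is
what the worked chain `4 + 3 + 2` implies (two additions for height 3); a
per-addition reading of "as many additions as the height" would contradict
that chain, so the chain wins. For the unknown-base guess we invert the
closed form `value = b·h − h(h−1)/2` and round. A midpoint-of-range guess
was considered and rejected: for `x $ 4 = 26` it guesses 6, undershoots
(18 < 26), and the ±1 rule then reports 7 — an error the task's subjects
(and the printed solution, 8) do not make. The arithmetic estimate reaches
the right base within ±1 everywhere in the design range (bases 4--9, heights
2--5), which is what the ±1 correction rule presumes.

Each trial's trace contains three visual encodings (`encode_step` = 0.3 s
each), one declarative retrieval per addition, one problem-state update per
chain step (`ps_step` = 0.2 s), one extra problem-state interval per carry
(`carry_extra` = 0.2 s; carries are detected as unit-digit sums ≥ 10), and
one right-hand mouse action per response digit plus submit
(`motor_step` = 0.75 s, a mouse move-and-click). Retrieval latencies draw
from a gamma distribution with mean `retrieval_mean` = 0.483 s — the
behavioral estimate for arithmetic-fact retrieval — and shape 2. The shape
is a modeling choice (only the mean is empirically anchored): shape 2 gives
a right-skewed, strictly positive latency distribution of the kind retrieval
processes produce, with SD ≈ 0.34 s; `retrieval_shape = Inf` degenerates to
a constant for exact reconstruction tests. Sessions pace trials as in the
scanner protocol: up to 30 s to solve, then 5 s feedback + 12 s distractor +
4 s fixation (21 s total) before the next onset; 72 trials, 18 per cell of
small/large base × small/large height.

**Threaded multitasking.** Three component tasks — visual tracking
(alternating visual samples and right-hand presses), tone counting (20 tones
over 30 s, 10--17 high tones incrementing a problem-state counter, count
reported in a 10 s response window), and a 2-back letter task (12 letters at
1000 ms on + 1500 ms blank; visual encoding, declarative retrieval of the
letter two back, problem-state update, left-hand response) — run singly or
in pairs. A greedy scheduler assigns each thread's ordered resource requests
to module timelines; a busy module queues the other thread
first-come-first-served. When two threads could start at the same instant,
the thread whose previous step completed earlier goes first; remaining ties
break by fixed task order (track < nback < count). Stimulus-locked steps
(tone and letter onsets) cannot start early. When both tasks need the
problem state (2-back with counting), every ownership handover inserts a
declarative store and retrieve — the swap that makes that condition the most
demanding. Counting responses use the right hand except alongside tracking,
which occupies it. Step durations (0.2--0.3 s) are schedule-level
stand-ins; continuous mouse motion between clicks during problem solving is
not modeled.

## From demand to BOLD

The hemodynamic response is the difference of two gamma densities,
`h(t) = g(t; 6, 1) − (1/6)·g(t; 16, 1)` on a 32 s support, the conventional
double-gamma parameterization; its peak lies at ≈ 5 s. Predictions are the
convolution of the sampled demand with this kernel, scaled by `dt` so the
result approximates the continuous integral, sampled at scan times (nearest
grid point; default `dt` = 0.1 s, TR = 2 s). Linearity is exact by
construction: the prediction of a trace equals the sum of its intervals'
predictions.

Demand is sampled by *fractional cell coverage*: cell `[t, t+dt)` takes the
fraction of it covered by activity. For grid-aligned intervals this is the
plain 0/1 indicator; for unaligned edges it keeps the sampled demand mass
exact, which is what makes predictions stable under `dt` refinement (halving
`dt` moves scan-sampled predictions by well under 1%; point sampling of
sub-second events does not achieve this). Predictions carry arbitrary units;
whenever they meet data, a scalar gain per module is fitted by least squares
(for RMSD) while TCC and R² are scale-free. Trial-locked condition averages
subtract the value at the onset scan as baseline — the simplest rule that
zeroes constant signals; no pre-onset scans are required.

A saturating/nonlinear BOLD model is deliberately out of scope; sustained
blocks therefore predict more accumulation than real data typically show.

## The GLM and group stage

Per subject, the design matrix holds one regressor per active module
(convolved demand, mean-centered, scaled to unit SD), polynomial drift
columns (order 1 by default) and an intercept. The unit-SD scaling is a
deliberate choice beyond plain centering: session schedules differ across
subjects, so raw regressor scale varies, and betas would carry that
variance into the group stage; standardized predictors make betas
"signal per unit-SD predictor", comparable across subjects. Empty-demand
modules are dropped with a warning; rank deficiency is reported with the
most collinear module pair. Voxelwise OLS yields betas and t values
(`df = scans − columns`); zero-variance voxels leave the mask. The group map
is a voxelwise one-sample t across subject betas (`df = n − 1`, two-sided p,
|t| capped at 10⁶ for zero-variance voxels). Dissociation between two
modules uses the difference of squared semipartial correlations per subject,
then the same group t — the positive tail marks regions where the first
module explains uniquely more variance.

Thresholding keeps voxels with `p < 10⁻⁷` (uncorrected, as the mapping
procedure specifies; no RFT/FDR at this step) and removes connected
components below the extent threshold. Connectivity is 26-neighborhood by
default (6 and 18 selectable) — the choice changes component counts, so it
is exposed and documented. Cluster labels order by descending peak |t|.

## Region growing, restriction, mirroring

From a suprathreshold component, `grow_region()` starts at the most
significant voxel (max |t|; a signed option exists) and repeatedly adds the
most significant suprathreshold voxel bordering the region until 100 voxels
are reached or the component is exhausted (the region is then reported
short, mirroring the 80-voxel anatomically-restricted manual region).
Ties break by lowest linear voxel index, making growth deterministic.
Anatomical restriction (`restrict_domain()`) intersects the growth domain
*before* growing, so the region is defined within the structure. Mirroring
reflects member voxels about the world-space midsagittal plane `x = 0` and
takes the nearest voxel — robust to affines whose midline falls between
voxel columns — flipping the hemisphere label; voxels reflected off the grid
are dropped with a count.

## The synthetic generator: what it emulates, what it does not

`make_truth()` places disjoint spheres (default radius 12 mm) at the
mapping's left-hemisphere centers — intraparietal sulcus (problem state),
inferior frontal sulcus (declarative), precentral gyrus (manual), superior
temporal gyrus (aural), middle occipital gyrus (visual) — on a
40 × 48 × 40 grid at 4 mm (MNI-like affine). These coordinates parameterize
ground truth only; no algorithm reads them. `simulate_subject_run()` builds
voxel series as `baseline + m·a·x̃ + drift + noise` inside a module's
region, where `x̃` is the module's convolved demand standardized to unit SD,
`a` the amplitude, and `m` a per-subject multiplier (mean 1, SD 0.2).
Standardizing `x̃` makes `a/σ` literally the per-voxel SNR (default 1 = 1 at
`baseline` 100, i.e. ≈ 1% signal change against 1% noise): without it,
sparse-demand modules (declarative) would have vanishing injected variance
while dense ones (tracking visual) would dominate, and no single amplitude
would be meaningful. Noise is white or AR(1) (`ar_rho`, marginal SD held at
σ). The generator does not emulate spatial noise correlation, physiological
noise, motion, susceptibility dropout, or BOLD nonlinearity — so passing
recovery tests demonstrate the *algorithms* are correct and calibrated, not
that real acquisitions of this size would yield the same power.

Two scale choices deserve note. First, ground-truth spheres default to
12 mm (≈ 113 voxels at 4 mm): recovery is scored against 100-voxel grown
ROIs, and regions at least as large as the growth target are the regime in
which Dice can approach 1. Second, the recovery pipeline's extent threshold
is scaled to voxel volume: 250 voxels at ≈ 2.5 mm acquisition resolution
corresponds to ≈ 50 voxels at 4 mm, and an unscaled 250 would exceed the
true regions themselves. The algorithmic default of `threshold_clusters()`
remains 250, as specified for acquisition-resolution maps.

Problem sizes in the validation suite — 18 subjects, 8 trials per run for
the full-circle recovery (five seeds), 3--6 subjects on reduced grids for
calibration checks — are chosen to exercise every stage at desk scale while
keeping the suite fast; the group-level t threshold at `p < 10⁻⁷`,
`df = 17` is ≈ 8.8, comfortably below the ≈ 17--20 the default SNR yields
in-region.

## Evaluation statistics

`tcc(x, y) = Σxy / √(Σx²Σy²)`: 1 for proportional vectors, −1 for exact
opposites, 0 for orthogonal ones; sensitive to sign and slope, defined for
flat curves, |TCC| ≤ 1 by Cauchy–Schwarz. R² (squared Pearson correlation)
is reported alongside precisely because it ignores what TCC keeps: R²(v, −v)
= 1 while TCC(v, −v) = −1. RMSD is computed after the per-module gain fit.
Aggregate statistics concatenate the per-condition curves rather than
averaging per-condition statistics — one number per module × mapping — and
the individual TCC is computed per subject on the same concatenation
(mean, SD, min, max). Whether aggregate congruence should concatenate or
average per-condition values is genuinely open; concatenation weighs
conditions by their length and preserves between-condition level
differences, which is the property the mapping comparison needs.

Behavioral filtering drops subjects at or below 85% accuracy (the retained
boundary is strictly above 85%), then trims correct trials with RT above
mean + 2 SD per subject × condition. The cut is one-sided — slow outliers
are the stated concern — and cells with fewer than two trials are left
unfiltered (SD undefined) and logged. Note a small-sample fact: with n ≤ 5
trials in a cell no point can exceed 2 sample SDs, so the trim only bites in
reasonably filled cells.

## Numerical and degenerate-input conventions

Voxel indices are 0-based in sidecars and world math; linear indices inside
R are 1-based; world coordinates are mm in MNI orientation (negative x =
left). Intervals are half-open in seconds. All randomness flows from
explicit seeds; group simulations derive subject seeds as `seed + s`.
Degenerate inputs error early and specifically: unknown module labels,
overlapping intervals, intervals beyond the sampled length, rank-deficient
designs (naming the collinear pair), grid mismatches, empty ROIs and empty
suprathreshold masks, zero vectors for TCC, zero variance for R². Empty
cluster sets are valid results, not errors.

## Known limitations

Schedule-level task simulation (no production system, no latency learning);
linear BOLD only; uncorrected voxelwise thresholding by design of the
mapping procedure; the dissociation statistic is a reasonable stand-in where
the original analysis is underspecified; synthetic noise is temporally but
not spatially structured. Fit values computed on synthetic data say nothing
about any real dataset's fit values — reproducing those would require the
original subject recordings, which is explicitly out of scope.
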