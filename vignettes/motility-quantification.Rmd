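---
title: "Quantifying bidirectional motor motility from traced kymograph tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bidirectional motor motility from traced kymograph tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymotility)
```

## The measurement problem

In single-molecule TIRF assays of microtubule motors, fluorescently labeled
complexes (for example dynein–dynactin recruited by the adapter HOOK3, with
or without the opposite-polarity kinesin KIF1C) land on surface-immobilized
microtubules and move along them. Each microtubule is summarized as a
kymograph — position along the microtubule on one axis, time on the other —
and each motor complex appears as a sloped or vertical line that an analyst
traces as a multisegmented polyline. The questions asked of such data are
quantitative: how often do complexes land, how far and how fast do they run,
how long do they stay attached, and in which direction do they travel —
including the rare complexes that reverse direction, the signature of
coupled opposite-polarity motors.

`kymotility` implements that quantification: validated track/context/manifest
tables, segmentation of traced polylines into runs and pauses,
directionality classification, motility metrics, hierarchical "superplot"
aggregation, the accompanying statistics battery, and a stochastic simulator
that generates ground-truth datasets with the same structure, so every stage
can be verified without raw movies.

## Data model and coordinate conventions

Positions are in nanometers along the microtubule axis and times in seconds
from the movie start. All thresholds below assume the **plus-end-positive**
convention, so tracks must be oriented first (`orient_tracks()`); kymographs
traced with the plus end to the left have their positions negated. Polarity
is an experimental fact (established, for example, by imaging a
kinesin-only channel after each assay) and is required input: the package
refuses to analyze contexts with `polarity = "unknown"` rather than guess.
Pixel size and frame interval are likewise per-context inputs, not assumed
constants, because different instruments were used for different assays
(105 nm and 0.136 s are typical values and are the simulator defaults).

Tracks are stored one vertex per row (`track_id`, `context_id`, `t_s`,
`x_nm`). Serialization uses 17 significant digits so a write/read round trip
is bit-identical.

## Segmentation and classification rules

Each pair of consecutive vertices is a segment with constant speed
`dx/dt`. The rules, all on traced segments as drawn:

* a segment is **static** iff |speed| < 25 nm s⁻¹ (so exactly 25 counts as
  moving);
* consecutive moving segments with the same sign merge into one **run**; a
  run ends when the motor falls static or reverses direction; run length is
  the sum of |dx| over its segments;
* **total run length** is the sum of all run lengths in both directions;
* classification applies, in order: total run length < 1,000 nm → *static*;
  runs in one direction only → that direction; more than 1,500 nm traveled
  in *both* directions → *bidirectional*; otherwise the majority direction
  (a track with 20,000 nm minus and 200 nm plus travel is *minus-end
  directed*).

The inequalities are strict exactly as stated: 1,000 nm total is not
static, 1,500 nm both ways is not bidirectional. An exact plus/minus tie
below the bidirectional threshold cannot be assigned a direction
non-arbitrarily; it is labeled bidirectional with a warning (it occurs only
in synthetic data).

Segmentation operates on the polyline vertices, not on per-frame resampled
positions. That matches the provenance of the data — an analyst traces
straight line segments through the kymograph, averaging out localization
scatter by eye — and it is why the classifier is robust to localization
noise. A per-frame sampled representation is available from the simulator
for users who want to study the difference.

```{r}
tr_t <- c(0, 4, 6, 10)
tr_x <- c(0, -2400, -2380, -4800)   # run, pause, run toward the minus end
seg <- compute_segments(tr_t, tr_x)
rp <- segment_runs(seg)
rp$runs
classify_track(rp$runs)$label
```

## Metrics and their units

* **Dwell time**: total time on the microtubule, pauses included.
* **Average speed**: total run length / dwell time (nm s⁻¹); a purely
  paused track has speed 0.
* **Landing rate**: tracks per kymograph width (nm) and movie length (s),
  ×60,000 to express it per µm per min. The factor is exactly
  1,000 nm µm⁻¹ × 60 s min⁻¹.
* **Processive events**: a complex qualifies iff it stays attached ≥ 1.2 s
  and moves ≥ 525 nm (both inclusive); 525 nm is five 105-nm pixels. Event
  frequency is reported per µm per s — note the *different* unit convention
  from landing rates; both carry units in every column name and are never
  mixed. Displacement is measured as total run length by default,
  consistent with the five-pixel rationale for a traced line; a
  net-displacement mode (`displacement = "net"`) is provided for stricter
  definitions.

One stated-threshold tension is documented rather than resolved: a 1.2 s
minimum dwell corresponds to about nine 0.136-s frames, not the five
frames the pixel rationale would suggest (0.68 s). The package uses 1.2 s
as the default because that is the stated criterion; both thresholds are
plain arguments.

## Superplot aggregation and statistics

Values are aggregated through the hierarchy condition → experiment → movie
→ microtubule. `aggregate_values()` returns, per condition, the
per-microtubule (or per-movie / per-experiment) values, per-experiment
means, and the pooled median, quartiles and 10th/90th percentiles — the
numbers a superplot draws. Directionality is reported both as pooled
fractions of all tracks and as per-experiment mean ± s.d.; the two differ
whenever experiments contribute unequal track numbers, so both are labeled
explicitly.

The testing battery mirrors standard practice for such data:

1. **Normality gate**: D'Agostino–Pearson K² on each group (α = 0.05 by
   default; the gate's α is a documented free choice). Samples smaller than
   20 are refused by the gate and route to the nonparametric path.
2. If all groups pass: pairwise Welch t tests, Holm-corrected.
3. Otherwise: Kruskal–Wallis H (tie-corrected), then Conover–Iman (default)
   or Dunn pairwise post hocs on pooled mid-ranks, Holm-corrected.

Statistics are computed on per-microtubule values by default — the
microtubule is the unit of observation — with per-track and per-experiment
modes available. All post hoc p values are two-sided; Holm is applied
within each metric's family of pairwise comparisons. K², Conover and Dunn
are implemented in the package (no installed R implementation exists) and
are verified in the test suite against independent reference computations
frozen at 10⁻⁸–10⁻¹⁰ agreement, alongside a simulated-null check that the
full battery holds its nominal type-I error.

```{r}
set.seed(1)
groups <- list(a = rlnorm(30, 0, 0.6), b = rlnorm(30, 0.4, 0.6),
               c = rlnorm(30, 0.9, 0.6))
res <- compare_groups(groups)
res$path
res$pairwise
```

## The simulator: what it emulates and what it does not

`simulate_trackset()` generates datasets with the statistical structure the
analysis assumes:

* **Landing**: Poisson with intensity λ (events µm⁻¹ s⁻¹) × microtubule
  length × movie duration; landing times and positions uniform.
* **Motion**: a continuous-time Markov process over {plus run, minus run,
  pause} with exponential dwells, per-state detachment rates, and
  truncated-normal speeds (CV 0.25 by default, no sign flips within a
  state). This is the simplest generator producing the run/pause/switch
  phenomenology the classifier must handle; it is a test harness, not a
  mechanochemical model of motor stepping or tug-of-war force balance.
* **Boundaries**: paths truncate at the microtubule ends (recorded as
  detachment) and at the movie end; end reasons are kept in the ground
  truth.
* **Observation**: the primary output is the *traced* track — the exact
  state-change polyline with i.i.d. Gaussian localization noise on its
  vertices. This emulates the manual-tracing step that produces the real
  input data. Raw per-frame noisy positions are deliberately *not* the
  primary representation: feeding them to a vertex-wise segmenter would let
  frame-to-frame noise (mean |Δx| = 2σ/√π per frame) masquerade as run
  length, which is precisely what human tracing suppresses. The per-frame
  table is also returned, for kymograph rendering
  (`render_kymograph()`: Gaussian PSF per molecule per frame, Poisson
  photon noise) and for studying that failure mode.

Ground truth carries each track's population, state log (which spans the
attachment interval exactly), end reason, and the label obtained by
applying the classification rules to the exact noise-free path
(`true_class()`), which is the recovery target for the pipeline.

Presets (`sim_preset()`): `"ddhk"` uses the measured directionality mixture
of the dynein–dynactin–HOOK3–KIF1C cocomplex (83.4% minus-directed, 13.4%
plus-directed, ~1.6% static, ~1.6% switching); `"ddh"`/`"hk"` are
minus-/plus-dominant controls; `"fhf"` mimics a sparse, weakly activated
dynein condition with a ~6,300 nm exponential mean run length. Per-state
speeds (600 nm s⁻¹ minus, 500 nm s⁻¹ plus), pause kinetics and landing
intensities are round free-choice values chosen to be realistic for
dynein-/kinesin-3-driven transport; published per-condition speeds appear
only as figures, not numbers, so no printed value constrains them.

## Numerical choices and edge cases

* Threshold ties: strict inequalities exactly as stated above.
* A track with two identical-position vertices is a valid pure pause.
* Degenerate statistics: all-identical data returns H = 0, p = 1 (not an
  error); constant samples make K² undefined and raise an error; post hoc
  variances of fully tied data collapse to zero and the statistics are
  defined as 0 (p = 1).
* Mid-ranks everywhere; tie corrections enter H and both post hoc variance
  terms.
* The run *count* is not monotone in the static-speed threshold (a slowing
  mid-segment can split a run in two); the moving-segment set and total run
  length are monotone, and the tests assert exactly those.
* Full determinism: a seed fixes the simulator bit-for-bit, and the
  analysis pipeline is deterministic, so reruns are byte-identical.

## Validation scale and limitations

The test suite validates landing-rate recovery on 200 simulated kymographs
(10 µm × 100 s at λ = 0.1 µm⁻¹ s⁻¹), run-length recovery on ~2,000
noise-free tracks (within 5% of the 6,000 nm exponential target), and
classification recovery on a four-population mixture at 20 nm localization
noise (per-class agreement with ground truth ≥ 95%, typically ≥ 99%); the
Kruskal–Wallis null calibration uses 10,000 replicates. These sizes give
comfortable Monte-Carlo margins for the stated tolerances.

Passing these tests shows the pipeline correctly implements its stated
rules and recovers parameters from data that satisfy the generator's
assumptions. Real kymograph data differ in ways the simulator does not
emulate: tracing error is correlated along a line rather than i.i.d. per
vertex; motors can pause at microtubule ends instead of detaching;
fluorophores photobleach; landing can be spatially nonuniform; and speeds
need not be truncated-normal. Conclusions about real data rest on the
correctness of the manual tracing, not on these tests. The package also
deliberately excludes automated track detection, changepoint/HMM
segmentation of noisy trajectories, and intensity-based analyses.
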