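# kymotility

Quantification of single-molecule motor motility from traced kymograph
tracks.

In TIRF assays of microtubule transport, labeled motor complexes — dynein
recruited by dynactin and a cargo adapter such as HOOK3, kinesins such as
KIF1C, or cocomplexes containing both — land on immobilized microtubules
and move along them. Each microtubule is summarized as a kymograph
(position × time), and each complex is manually traced as a multisegmented
line. This package turns those traced polylines into the numbers such
studies report, and ships a ground-truth simulator so the whole pipeline is
testable without raw movies. It is written for in vitro motility labs and
for anyone who wants the analysis rules stated precisely and executed
reproducibly.

## What it computes

Given per-vertex track tables, per-kymograph contexts (length, duration,
pixel size, frame interval, polarity) and an experiment manifest:

* **Runs and pauses** — each traced segment has speed `dx/dt`; segments
  with |v| < 25 nm s⁻¹ are static, same-sign moving segments merge into
  runs, and a run ends at a pause or a direction reversal.
* **Directionality** — applied in order: total run length < 1,000 nm →
  *static*; one direction only → *plus*/*minus*; > 1,500 nm in both
  directions → *bidirectional*; otherwise the majority direction (20,000 nm
  minus with 200 nm plus is still *minus*).
* **Metrics** — total/plus/minus run length (nm); dwell time (s, pauses
  included); average speed = total run length / dwell time (nm s⁻¹);
  landing rate = tracks / (width · duration) × 60,000 (µm⁻¹ min⁻¹);
  processive events (≥ 1.2 s and ≥ 525 nm, i.e. five 105-nm pixels) and
  their frequency (µm⁻¹ s⁻¹).
* **Superplot aggregation** — per-microtubule values, per-experiment means,
  pooled median/quartiles/10–90% whiskers, per condition.
* **Statistics** — D'Agostino–Pearson K² normality gate; if any group is
  non-normal, Kruskal–Wallis *H* followed by Conover–Iman (or Dunn) post
  hocs on pooled ranks with Holm–Bonferroni correction; Welch t tests
  otherwise.
* **Simulation** — Poisson landing, continuous-time Markov switching
  between plus-run/minus-run/pause states, exponential dwells, detachment,
  truncated-normal speeds, localization noise, ground-truth labels, and
  synthetic kymograph images (Gaussian PSF + Poisson noise).

## Worked example

Simulate a mixed bidirectional condition with three experiments, analyze
it, and compare against the simulator's ground truth:

```r
library(kymotility)

params <- sim_preset("ddhk", seed = 42, n_experiments = 3,
                     movies_per_experiment = 2, mts_per_movie = 5)
sim <- simulate_trackset(params)

vertices <- orient_tracks(sim$tracks, sim$contexts)
cls <- classify_tracks(vertices)
table(cls$label)
#> bidirectional         minus          plus        static
#>            15          1411           195           518

mt <- per_mt_metrics(vertices, sim$contexts)
aggregate_values(mt, sim$manifest, "landing_rate_um_min")
#> Superplot summary of 'landing_rate_um_min' at level 'mt'
#>   ddhk: n = 30 (30 mt / 6 movies / 3 experiments), median = 1.788 [q1 1.594, q3 1.919]

m <- merge(cls[, c("track_id", "label")],
           sim$truth[, c("track_id", "true_label")])
mean(m$label == m$true_label)
#> [1] 0.993
```

2,139 complexes landed; two thirds run to the minus end (dynein-driven),
~9% to the plus end (kinesin-driven), a quarter are static — the simulated
mixture is 83/13/2/2 by *population*, but short-lived walkers legitimately
classify static under the 1,000 nm rule, which is why ground-truth labels
(not population names) are the recovery target: 99.3% of tracks get their
true label back despite 20 nm localization noise. The landing-rate
superplot summarizes 30 microtubules into the median and quartiles a figure
would draw.

The numbered scripts under `analysis/` run the same workflow at study
scale: `01_simulate.R` builds four conditions (minus-dominant, plus-
dominant, mixed, sparse), `02_classify.R` analyzes them and reports label
recovery, `03_metrics.R` pools per-microtubule metrics into superplot
tables, `04_stats.R` runs the gated statistics battery across conditions,
and `05_recovery.R` sweeps landing rate and noise to produce a parameter-
recovery table. All outputs land under `results/`.

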