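# tdrstates

Dive reconstruction and latent behavioural states from low-resolution
(5-minute) time–depth-recorder data on air-breathing marine
vertebrates.

Satellite-relayed TDR tags trade resolution for deployment length: a
tag that transmits one depth reading every 300 s can follow a sea
turtle for most of a year, but at that resolution dive boundaries are
uncertain, fast successive dives merge into single records, and
sub-interval dives disappear. `tdrstates` is for movement ecologists
working with such data. It provides:

* **Dive reconstruction** — zero-offset correction of sensor drift,
  threshold dive detection (3 m) with boundary times interpolated on a
  10 s grid, descent/bottom/ascent phase labelling (bottom = depth over
  80% of the dive's maximum), and kinematic splitting of merged dives
  where an unobserved surfacing was possible within one sampling
  interval.
* **Behavioural states** — a multivariate hidden Markov model over
  four per-dive features (maximum depth, bottom time, dive time,
  post-dive surface interval; log + range transformed), with
  diagonal-Gaussian emissions, fitted by Baum–Welch EM over multiple
  trip sequences, selected among 2–5 states by best-of-restarts AIC,
  and decoded by Viterbi. For `K` states and `p` features,
  `AIC = 2[(K−1) + K(K−1) + 2Kp] − 2 log L`.
* **Validation** — a high- vs low-resolution comparison: detect dives
  at 1 s and on the 300 s point-resampling, bin maximum depths in 10 m
  intervals, compare the distributions with Fisher's exact test.
* **Track context** — Argos filtering (near-duplicates, class Z,
  speed/distance/angle spikes), trip splitting at 7-day gaps,
  move-persistence median-split classification, time-join of dives to
  fixes.
* **Seasonality** — cyclic cubic regression spline (6 knots, periodic
  over the year) binomial models of monthly state occupancy, and
  pairwise tests of move-persistence class across states.
* **A synthetic-data module** — labelled dive sequences from a 4-state
  Markov chain with lognormal metrics, rendered depth traces, sensor
  drift, point-resampling and contaminated Argos tracks, all with
  ground truth retained, so the entire pipeline is testable end to end.

## Worked example

Simulate a month of diving, render the 1 s trace, resample to 300 s,
and reconstruct:

```r
library(tdrstates)

cfg <- sim_config()                       # 4 canonical states
dv  <- simulate_dive_sequence(cfg, 300, seed = 7)
ser <- render_depth_series(dv, dt = 1)    # 1 s depth trace

det <- detect_dives(ser)                  # native resolution
low <- resample_series(ser, 300)          # 5-minute tag output
dl  <- label_phases(detect_dives(low))
sp  <- split_merged_dives(dl, nominal_dt = 300)

c(true = nrow(dv), at_1s = nrow(det), at_300s = nrow(dl),
  after_split = nrow(sp))
#>        true       at_1s     at_300s after_split
#>         300         300         278         298
```

At 1 s every dive is recovered (the 300 detected maxima match the
generated maxima exactly); at 300 s, 22 dives are lost to merging and
splitting restores 20 of them. Fit and decode the state model on the
generator's features:

```r
feats <- data.frame(individual_id = "sim", max_depth = dv$max_depth,
                    bottom_time = dv$bottom_time,
                    dive_time = dv$dive_time,
                    surface_interval = dv$surface_interval)
X    <- fit_transform(feats)$X
sel  <- select_model(X, states = 4, n_restarts = 5, base_seed = 7)
fit  <- sel$fits[["4"]]
summ <- summarise_states(fit, decode(fit, X), feats)
round(summ$fit$A, 2)      # canonical-label transition matrix
mean(summ$state == dv$state)
```

On 5,000 dives this recovers every transition probability within
±0.03 and labels 99.6% of dives with the generating state (see
`scripts/acceptance.R` output below).

## The analysis workflow

The `analysis/` directory runs a complete synthetic study — four
deployments staggered across the calendar year, 100 days each at 300 s
(≈ 9,000 dives) — through the pipeline, writing tables under
`results/`:

| script | what it does |
| --- | --- |
| `01_simulate_deployments.R` | depth traces (with drift) + Argos tracks with move persistence |
| `02_reconstruct_dives.R` | zero-offset correction, detection, phases, splitting |
| `03_dive_features.R` | features, exclusions (first 24 h, ≤ 10 m, gaps), transform |
| `04_fit_hmm.R` | HMMs for 2–5 states, AIC table, decoding, transition matrix |
| `05_validation_and_season.R` | resolution validation, seasonal curves, MP × state tests |

Step 4 prints, for the synthetic study, a diagonally dominant
transition matrix (self-transitions 0.62–0.84) whose canonical states
reproduce the generator's structure (state 1: longest bottom time
2762 s; state 2: deepest, 84 m; state 3: shortest dives, 794 s;
state 4: shallowest, 16 m). Step 5 recovers the seasonal design
(state 3 occupancy peaking at month 6.7, state 1 in winter) and finds
`p = 0.783` for the high- vs low-resolution depth-distribution
comparison.

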