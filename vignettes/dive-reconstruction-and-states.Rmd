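---
title: "Reconstructing dives and behavioural states from 5-minute depth records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing dives and behavioural states from 5-minute depth records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrstates)
```

Satellite-relayed time–depth recorders on sea turtles and other
air-breathing marine vertebrates often transmit one depth reading every
five minutes. At that resolution individual dives are still visible,
but their boundaries are uncertain, fast successive dives merge into
single records, and sub-five-minute dives vanish entirely. `tdrstates`
implements a complete pipeline for this setting: dive reconstruction
from the raw depth trace, a validation protocol against high-resolution
data, a multivariate hidden Markov model (HMM) of per-dive behavioural
states, and seasonal and horizontal-movement analyses of the decoded
states. A synthetic-data module generates labelled dive sequences and
Argos-like tracks so that every stage can be scored against known
ground truth.

This vignette is the package's account of the methods: the models and
their assumptions, the tunable parameters and why their defaults are
what they are, what the simulator does and does not emulate, and the
numerical choices that matter.

## The synthetic study

`sim_config()` defines the generative model used throughout the tests:
a first-order Markov chain over four behavioural states and, within
each state, independent lognormal distributions for maximum depth (m),
bottom fraction of dive time (unitless, capped at 0.95), dive time (s)
and post-dive surface interval (s). Lognormal emissions mirror the log
transform applied to the skewed features before fitting; independence
within state is the simulator's assumption, chosen for transparency,
not an empirical claim about turtles.

The four default states follow the qualitative structure repeatedly
reported for loggerhead diving: state 1 has an intermediate depth
(median 30 m), the longest bottom and dive times (0.8 × 3600 s) and a
short surface interval (120 s) — resting-type dives; state 2 is
deepest (80 m) with a long surface interval (1800 s); state 3 has the
least bottom time, the shortest dives (700 s) and the longest surface
intervals (3600 s); state 4 is shallowest (15 m) with the shortest
surface intervals (60 s). The default transition matrix is diagonally
dominant (self-transitions 0.65–0.83) and the default initial
distribution favours state 3, matching the persistence structure
reported for free-ranging deployments. These defaults deliberately
exercise the canonical labelling rule (below).

Monthly occupancy modulation is available per state
(`season_amplitude`, `season_peak_month`): the probability of entering
state *k* is reweighted by
$1 + a_k \cos(2\pi (m - m_k)/12)$, floored at 0.05. The default
amplitude is 0 — the chain is time-homogeneous unless a study design
calls for seasonal structure (the bundled analysis scripts switch it
on). Modulating the *entry* probabilities keeps within-month dynamics
Markovian while producing smooth seasonal occupancy cycles.

`render_depth_series()` draws each dive as a piecewise-linear profile:
linear descent to 80% of maximum depth over `(dive_time −
bottom_time)/2`, a symmetric excursion to the maximum occupying exactly
`bottom_time` at depths ≥ 0.8 × max, and the mirror-image ascent. This
trapezoid-with-apex shape is the simplest geometry whose rendered
bottom time (time spent over 80% of maximum depth) equals the generated
bottom time by construction. The apex is snapped to the sampling grid
so that at the native resolution the sampled maximum equals the
generated maximum exactly; this makes round-trip tests sharp rather
than discretisation-limited. The simulator does not attempt
hydrodynamic or energetic realism, dive-shape diversity (U/V/S
profiles beyond the trapezoid), depth-dependent sensor resolution, or
an Argos error-ellipse model — so passing round-trip tests demonstrate
the correctness of the reconstruction logic, not its performance on
the full variability of real traces.

`resample_series()` emulates a tag reporting instantaneous depth once
per interval by point-sampling (nearest reading at or before each grid
time), never averaging. Real on-board compression adapts resolution to
the dynamic range within each interval; that behaviour is proprietary
and is deliberately not emulated.

## Dive reconstruction

**Zero-offset correction.** Pressure sensors drift, so surface readings
wander away from 0 m. `zero_offset_correct()` estimates the surface
offset as the 5th percentile of depth in 3-hour windows, takes a
running minimum over ±2 windows, interpolates the window estimates to
every reading time, subtracts, and clamps at ≥ 0. The running minimum
is there because windows dominated by continuous diving inflate the
local quantile: anchoring each window to the lowest nearby estimate
keeps the correction tied to the most recently surfaced window. The
residual bias is bounded by the drift accrued over the ±2-window span
(≈ 0.3 m at 0.5 m/day); both window length and quantile are exposed.

**Dive detection.** Readings deeper than 3 m (the conventional dive
threshold for turtle TDR work) form candidate dives. Boundary times
are refined on a 10 s grid anchored at the bracketing surface reading:
the start is the earliest grid time at which linearly interpolated
depth reaches the threshold, the end the latest. On a 1 s series the
10 s grid is coarser than the data and boundaries collapse to reading
times, which is the intended behaviour. Dives whose readings span a
gap longer than 1.5 × the nominal interval are flagged `internal_gap`
and excluded downstream; 1.5 is the smallest factor that cannot
misfire on jittered but complete sampling.

**Phase labelling.** The bottom phase is the single contiguous span
between the first and last grid time at which depth exceeds 80% of the
dive's maximum ("over 80%" is read strictly; the alternative convention
shifts boundaries by at most one grid step). Mid-dive excursions above
the 80% line therefore remain "bottom" until splitting handles them,
which keeps bottom time well defined before segmentation. Grid times
before the bottom span are descent, after it ascent, so phase durations
sum to the dive duration exactly.

**Splitting merged dives.** At 300 s sampling, two dives separated by
a sub-interval surface visit appear as one record with an interior
"peak" (a local depth minimum). `find_dive_peaks()` reports local
minima strictly inside the dive with prominence — the shallower
adjacent reading minus the peak depth — over 1 m; runs of equal depth
bounded by deeper readings are plateaus, reported once.
`decide_split()` asks whether the animal could have surfaced
unobserved: the ascent rate into the peak and the descent rate out of
it each imply a time to cover `peak_depth − threshold`; if either is
within one sampling interval, the record is split. Plateau peaks
(ascend–hold–descend) split unconditionally, as an explicitly distinct
case; the speed quantities are still computed and logged. The first
half ends where the projected ascent crossed the threshold
(`peak_time + t_up`), the second begins where the projected descent
re-crossed it (`next_time − (next_depth − threshold)/v_down`), with the
second boundary clamped to follow the first. Placing both imputed
crossings inside the unobserved gap after the peak reading keeps every
recorded sample inside exactly one half (the peak reading closes the
first), so splitting conserves samples, never decreases the dive count,
and never increases total in-dive time. Recursion re-examines each
half and is capped at 4 splits per original record to guarantee
termination on pathological traces.

## Features and exclusions

Four features per dive feed the state model: maximum depth, bottom
time, dive time and post-dive surface interval (time from the end of
this dive's ascent to the start of the next; the deployment's final
dive has none and is dropped). Because boundaries are taken at the 3 m
crossing, measured surface intervals include the sub-threshold tails of
ascent and descent — a property of the boundary convention, visible in
the round-trip tests.

Exclusions follow standard practice: dives in the first 24 h after
deployment (handling recovery), dives at or below 10 m (unreliable at
5-minute resolution — the validation stage below is the empirical basis
for this cut-off), and dives containing transmission gaps. Each dive is
counted under one reason with precedence gap > first-day > shallow, so
the exclusion counts and the retained count always partition the input.

Maximum depth, dive time and surface interval are natural-log
transformed (right-skewed); bottom time is left raw; all four are then
min–max scaled to [0, 1] with ranges pooled over the full dataset —
log first, then scale, so the scaled features genuinely span [0, 1].
A 1 s epsilon guards the log of zero-length intervals that splitting
can produce. The fitted `transform_spec` is persisted so held-out data
transforms identically.

## The hidden Markov model

`fit_em()` fits, by Baum–Welch EM in scaled form, an HMM whose
emissions are independent Gaussians per feature within state (diagonal
covariance — the convention of the mixture-model packages used for
this class of problem, and the source of the parameter count
$(K-1) + K(K-1) + 2Kp$). Observation sequences are trips: chains do
not bridge deployment boundaries or multi-day track gaps, because a
Markov chain should not be asked to explain a data void. Convergence
is declared at a relative log-likelihood change below 1e-6 (cap 500
iterations); emission standard deviations are floored at 1e-4 and
hitting the floor is flagged; a non-finite likelihood marks the fit
non-converged rather than raising.

Initialisation draws emission means from the observations with
k-means++-style seeding, standard deviations from the pooled
per-feature s.d., and the initial distribution and transition rows from
Dirichlet(1). `select_model()` runs a ladder of seeded restarts
(restart *r* uses `base_seed + r`, so any single restart can be
reproduced alone) for 2–5 states and retains the lowest-AIC converged
fit per state count. The AIC table informs the choice of state count
but does not dictate it: with flexible emission models AIC typically
keeps improving with K, and the decision of whether a fifth state is
biologically distinct is the analyst's. Five states is the ceiling on
interpretability grounds.

Decoding uses Viterbi (ties broken towards the lowest state index, a
documented arbitrary choice) plus forward–backward posteriors.
Correctness of both recursions is established against exhaustive path
enumeration on small instances — the brute-force oracle is independent
of the recursions it checks.

**Canonical labelling.** Likelihood is invariant to permuting state
labels, so fitted states are relabelled by raw-scale structure: state 1
= largest mean bottom time, state 2 = deepest of the rest, state 4 =
shallowest, state 3 = the remainder. If two criteria select the same
state the rule falls back to pure depth ordering with a warning. On
synthetic data generated from the default configuration the canonical
labels coincide with the generator's labels, which is what makes
cross-run comparisons of transition matrices meaningful.

## Resolution validation

`compare_resolutions()` reproduces the high- versus low-resolution
protocol: detect dives on a native 1 s trace and on its 300 s
point-resampling, pool maximum depths deeper than 10 m into half-open
10 m bins, and compare the two frequency distributions with Fisher's
exact test. For 2×2 tables the p-value is the exact probability-order
two-sided value; 2×K tables use the exact network algorithm up to a
total of 200 and a seeded Monte-Carlo estimate (with reported standard
error) beyond. Splitting is not applied in this comparison — it
isolates what point-sampling alone loses. Two systematic effects are
worth knowing: the low-resolution arm can only miss dives (its count is
never larger), and point-sampled maxima undershoot the true apex by up
to the apex slope times half the interval, which can move dives near a
bin edge into the adjacent bin.

## Seasonality and move persistence

Monthly per-individual counts of dives in each focal state (months
without dives are absent, not zero-filled) are modelled as
binomial-logit regressions on a cyclic cubic regression spline of
month — 6 knots equally spaced on the period [1, 13), so the curve and
its first two derivatives agree across the December–January seam —
plus per-individual intercepts. The per-individual intercepts are a
fixed-effect simplification of the random effects used with
mixed-model machinery, and no AR(1) residual term is included: the
package's acceptance surface for this module is seasonal-shape
recovery (a flat simulation yields a near-flat curve; a sinusoid
peaking in July is recovered to within a month), not variance
components. The cyclic basis is a partition of unity, so one column is
dropped against the intercept for identifiability; this changes the
parameterisation, not the function space. Rotating month labels leaves
the fit invariant exactly when the rotation maps the knot lattice onto
itself (multiples of 12/5 months at 6 knots) and approximately
otherwise. Complete separation triggers a ridge-penalised IRLS
fallback (penalty 1e-6, flagged).

Move persistence *g* ∈ [0, 1] is consumed, not fitted: state-space and
move-persistence models are external published methods. Fixes are
classified by the per-individual median (g below the median =
localised; at or above = transiting, so at least half of each
individual's fixes transit). Dives join the nearest fix within 1 h
(half a 2-h regularisation interval). The association between
move-persistence class and state is tested with two-proportion z-tests
over all state pairs under Holm adjustment — a conservative,
dependency-free substitute for Tukey contrasts on a binomial GLM.
Because both the states and *g* are autocorrelated in time, a
median-split association on real or realistic data can reflect shared
seasonal structure rather than a dive-level link; the synthetic study
in `analysis/` shows exactly this behaviour.

## Track filtering

Argos processing uses the standard sequence: near-duplicates within
2 min of the previously retained fix are dropped (greedy, first fix
kept); class-Z fixes are removed; then a speed pass (great-circle
speed over 5 km/h to the previously retained fix removes the later
fix, with endpoints protected) and an angle pass (interior vertices
with turning angle under 15°/25° and both adjacent segments over
2.5/5 km) iterate to a fixed point. Distances are haversine on a
6371 km sphere. Whether the angle rule should require both or either
adjacent segment to exceed the length threshold is ambiguous in common
descriptions; both-segments is implemented. Tracks split into
independent trips at gaps strictly exceeding 7 days.

## Problem sizes and determinism

Every stochastic component is seeded, and the test suite fixes all
seeds, so the suite is deterministic. The bundled checks run at desk
scale: 200 random small instances for the enumeration oracles, 5,000
dives for HMM parameter recovery with 20 restarts, a 30-day 1 s trace
(≈ 740 dives over 10 m) for the reconstruction round trip, 20
individuals × 12 months × 100 dives for the seasonal recovery, and
1,000-fix tracks for filter scoring. The `analysis/` scripts run a
four-deployment, 100-day synthetic study (≈ 9,000 dives) through the
complete pipeline; `scripts/acceptance.R` recomputes the headline
quantities from scratch at the same scales under a caller-supplied
seed.

## Known limitations

* The simulator's trapezoidal dive geometry and within-state feature
  independence understate the variability of real dive profiles;
  recovery results bound what the algorithms can do under their own
  assumptions, not field performance.
* Zero-offset correction assumes the animal surfaces at least once
  within a few window lengths; long continuously-submerged stretches
  would be overcorrected.
* Splitting reconstructs at most one unobserved surfacing per peak and
  cannot recover dives shorter than the sampling interval that leave
  no interior reading at all.
* The seasonal model's fixed-effect intercepts understate uncertainty
  relative to a mixed model with REML smoothing and AR(1) residuals;
  fitted curves are comparable, standard errors are not reported.
* Move-persistence values are taken as given; errors in the upstream
  state-space fit propagate unexamined.
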