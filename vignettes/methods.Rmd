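---
title: "Measuring leader-follower information flow in tandem running"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leader-follower information flow in tandem running}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemflow)
```

## The question and the approach

During a tandem run one insect (the leader) guides another (the follower)
along a route, the follower keeping close contact behind the leader. Ants
and termites perform outwardly similar tandem runs with similar short-range
signals, yet use them for different ends -- route teaching versus mate
cohesion. The difference, if it exists, lives in the *communication
protocol*: who predicts whom, about what, over intermediate time scales.

`tandemflow` quantifies this with symbolic transfer entropy. Each runner's
trajectory is coarse-grained into a symbol series describing one behavioral
channel -- turning direction (rotation), stop-and-go behavior (pausing), or
both at once (compound) -- and the directed predictive information between
the two series is estimated in bits. Measuring *several* channels of the
same interaction separately is the point: the protocols differ not in
whether information flows, but in which channel flows in which direction.

## Encodings

Trajectories are tables of positions $(q_1, q_2, \dots)$ in millimetres at
a chosen sampling period. Three encodings are provided:

* **Pausing** (alphabet M/P): step $i$ (from $q_i$ to $q_{i+1}$) is a
  pause if its length is at or below a threshold, otherwise motion. The
  threshold is the $q$-th percentile (default 10) of step sizes pooled
  over all individuals of a dataset at that sampling period, with linear
  interpolation between order statistics (`stats::quantile` type 7). Step
  sizes of tandem runners are bimodal -- a low mode from pauses plus
  centroid-tracking jitter, a high mode from sustained motion -- so a
  low-percentile threshold isolates the pause mode; robustness to the
  exact percentile is checked by `threshold_perturbation()` over
  $q \in \{5,\dots,15\}$.
* **Rotation** (alphabet CW/CCW): the sign of the 2-D cross product of
  successive displacement vectors. An exactly zero cross product
  (collinear or stationary motion) copies the previous symbol; a zero run
  at the start of a track takes the first signed symbol that follows, and
  a fully collinear track is an error rather than a guess. No angular
  tolerance is applied: only exact zeros are treated as collinear.
* **Compound** (alphabet P/CW/CCW): pauses are mutually exclusive with
  rotation, so the pausing symbol overrides the turn symbol wherever it
  is P.

A track of $n$ positions yields $n-1$ pausing symbols (indices
$1..n-1$) and $n-2$ rotation symbols (indices $2..n-1$). Whenever series
must be aligned -- for the compound encoding or any joint leader/follower
computation -- leading entries are dropped to the common index range,
preserving the future-prediction direction.

### Sampling conventions

Subsampling keeps frames $n, 2n, 3n, \dots$, so a track of $N$ positions
keeps $\lfloor N/n \rfloor$. Periods are only accepted when they are an
integer multiple of the native frame interval within four-decimal
rounding. Cross-study tables conventionally report counts as
$\lfloor \text{duration}/\text{period} \rfloor$ with the period printed at
four decimals; `expected_sample_count()` implements that convention, which
can differ from actual decimation by one sample (at a printed 0.1668 s
over 900 s: 5395 versus 5394). Both numbers are exposed rather than
reconciled silently.

## The estimator

For destination series $D$ with history length $k$ and source series $S$,
transfer entropy is

$$T_{S \to D} = \sum p(d_{i+1}, d_i^{(k)}, s_i)\,
  \log_2 \frac{p(d_{i+1} \mid d_i^{(k)}, s_i)}{p(d_{i+1} \mid d_i^{(k)})},$$

with all probabilities estimated by plug-in block frequencies. Only the
source's *present* symbol conditions the future (source history length 1).
Counting is sparse -- keyed on observed blocks only -- because a binary
alphabet at $k = 20$ has over $2^{21}$ potential blocks while a series can
realize at most its own length; dense tables are never built. Blocks never
cross trial boundaries; pooled estimates sum counts over trials (behavior
is treated as a species property, not a pair property), while per-trial
estimates (one per tandem run) feed the nonparametric tests.

Useful exact identities hold by construction and are enforced in the test
suite at `1e-12` or better against an independent dense-enumeration
oracle:

* $T_{S \to D} = H(D_{i+1} \mid D^{(k)}) - H(D_{i+1} \mid D^{(k)}, S)$;
* the per-step log-ratio (*local* transfer entropy, which may be negative
  at misinformative moments) averages exactly to the pooled estimate;
* $0 \le T \le H(D_{i+1} \mid D^{(k)}) \le \log_2 |\mathcal{A}|$.

Derived quantities: **net** transfer entropy $T_{L\to F} - T_{F\to L}$
(sign = predominant flow direction) and **normalized** transfer entropy
$T / H(D_{i+1} \mid D^{(k)})$, the fraction of the destination's remaining
uncertainty explained by the source. Whether the numerator of the
normalized value should be raw or surrogate-corrected is genuinely open;
both are available (`normalized_te(te, correction = )`), the default is
raw, and `te_report()` prints raw and corrected side by side.

## Surrogates, correction, and tests

Plug-in estimates on finite data are biased upward. The null/correction is
built by re-pairing: each leader is matched with the follower of a
*different* trial (a uniform random derangement, by rejection sampling),
preserving every marginal series while breaking within-pair coupling. Over
`n_replicates = 50` re-pairings this yields an ensemble whose mean is
subtracted from the experimental estimate (`corrected_te()`); corrected
values may be negative and are reported as-is.

Two spreads of that ensemble matter and both are exposed:

* `se_bits` = sd/$\sqrt{50}$, the uncertainty of the *correction* (this is
  what a mean +/- SE table column reports);
* `sd_bits` = the ensemble standard deviation, which is the standard error
  of a *single* TE estimate under the re-pairing null. An experimental
  estimate is one draw from that null when no coupling exists, so
  significance-style z-scores divide by `sd_bits`. Dividing by `se_bits`
  would reject essentially always, even for truly independent pairs.

Hypothesis tests mirror standard practice for these designs: a one-sided
two-sample Wilcoxon rank-sum test (normal approximation with continuity
correction; the statistic is the Mann-Whitney count, maximum $n_1 n_2$)
compares per-trial experimental TE against per-pair TE of one surrogate
replicate -- the only comparison-set choice consistent with the
statistic's range for 20 trials -- and a one-sided paired Wilcoxon
signed-rank test (V = sum of positive-difference ranks, maximum
$n(n+1)/2$) compares the two directions on the same trials.

## Parameter selection

The analysis has two free parameters: the sampling period and the history
length $k$. `sweep_net_te()` evaluates pooled net TE over $k \in 1..20$
crossed with 45 periods (the integer multiples of the native frame
interval, 0.0334 s to 1.5015 s at 29.97 frames/s) -- 900 configurations --
refitting the pause threshold at every period. Cells where any trial has
fewer than $k+1$ symbols are invalid and excluded (not zero-filled).
`select_max_config()` picks the cell maximizing $|$net TE$|$: magnitude
rather than signed value, because the follower can legitimately be the
predominant source (the ant pausing channel), and a signed maximum would
never select such a configuration. Ties break toward smaller $k$, then
shorter period (the more parsimonious model). The sweep is raw
(uncorrected): running 50 surrogate replicates for each of 900 cells buys
nothing for *selection*, and the correction is applied at the selected
configuration only.

## Distance-resolved flow

`local_transfer_entropy()` + `pair_distances()` +
`local_te_by_distance()` show *where* (at which leader-follower
separation) each channel carries information: local TE is binned by
inter-centroid distance in body lengths (equal-width 0.1-BL bins -- the
standard figures plot smoothed conditional means, so the bin width only
affects intermediate reporting and is a knob), then smoothed with LOESS
(span 0.3, degree 2, bin counts as weights). Before smoothing, the
count-weighted bin means conserve the pooled TE exactly.
`speed_by_distance()` classifies each step by the sign of the distance
change (zero changes inherit the previous class, mirroring the collinear
rule; an all-zero series defaults to "increasing") and profiles each
role's speed on the closing and opening branches. Distances use the
species mean body length as the unit (2.34 mm for *T. rugatulus*, 8.89 mm
for *C. formosanus*, 5.5 mm for *R. speratus*) so regimes are comparable
across species. Fewer than 10 occupied bins fall back to raw bin means
(LOESS at span 0.3 is not meaningful there).

## The synthetic protocol generator

Because the package must be testable without animal recordings,
`simulate_tandem_pair()` generates coupled walkers under three protocols
with *known* ground-truth flow directions (`ground_truth()`):

* **ant** -- the leader turns persistently (a two-state Markov chain over
  turn direction) and drives the route; the *follower* initiates search
  pauses (geometric bouts); the resulting gap growth halts the leader
  beyond `d_stop_bl` body lengths and the follower's return releases it
  below `d_go_bl`. Expected flows: rotation leader-to-follower, pausing
  follower-to-leader -- the acknowledgment structure.
* **termite** -- the leader drives the route *and* pauses spontaneously;
  the pursuing follower (speed-capped at a contact standoff) halts when
  the leader halts. Both flows leader-to-follower.
* **independent** -- two uncoupled persistent walkers with spontaneous
  pauses sharing nothing, including initial conditions. No flow.

Defaults are chosen once for realism at the recorded study scale: 29.97
frames/s, 900-s trials, arena 370 x 655 mm (ant) or a 145-mm dish
(termite), body lengths 2.34 / 8.89 mm, walking speeds 2-2.6 mm/s (ant)
and 10-12 mm/s (termite), turn persistence time 2 s at 60 deg/s, follower
search-pause rate 0.05/s with 4-s mean bouts (long enough that a typical
bout at leader speed 2 mm/s grows the gap past `d_stop_bl` = 3 body
lengths, which is what makes the pausing channel causal rather than
incidental), and 0.05-0.1 mm centroid jitter, which reproduces the bimodal
step-size distribution that motivates the percentile threshold.

What the generator does *not* emulate: pheromone fields, antennation
micro-dynamics, corridor geometry, route memory, or any heterogeneity
between individuals. Passing recovery tests therefore shows that the
pipeline detects the directional structure these protocols embed at
realistic scales and noise levels -- not that real ants follow these exact
dynamics.

## Problem sizes and numerical choices in the checks

The test-suite and acceptance-script scales are the package's own
choices: protocol recovery runs 20 master seeds per protocol with 20
pairs of 900 s at a reduced 10 Hz (the information structure lives at
0.1-1 s time scales, so the native 29.97 Hz adds cost but no signal),
analysed at a 0.5-s period with $k = 3$ and 50 surrogate replicates.
Recovery demands the correct sign *and* $|z| > 3$ ensemble spreads in at
least 95% of seeds (ants, termites); the independent protocol demands
$|z| < 2$ in at least 90%. Estimator-versus-oracle checks run on all
series up to length 12, alphabets up to 3 symbols, $k \le 3$, at
`1e-12`; estimator-consistency and type-I checks use 200 replicates.

Known limitations:

* The re-pairing null is *conditional* on the observed series. For the
  rotation channel of simulated uncoupled walkers its spread is mildly
  narrower than the across-dataset spread (null z sd up to ~1.2 in
  batches of 20 seeds), plausibly because all walkers share one arena
  geometry; the fraction of seeds inside +/- 2 spreads then hovers near
  its nominal 0.9. On symbol-level iid nulls the same z is well
  calibrated (sd ~0.93).
* Plug-in estimates at large $k$ on short series are strongly biased;
  the surrogate correction removes the bulk but comparisons across $k$
  should stay within a sweep, not across datasets of different lengths.
* Trials shorter than $k+1$ symbols are skipped with a warning
  (pooled/per-trial estimation) or invalidate the sweep cell; gapped
  tracks are rejected outright rather than interpolated, since
  interpolation would inject autocorrelation into exactly the quantity
  being measured.
* Termite trials are required to have the full configured duration; a
  shorter recording is surfaced as an error, not silently truncated.

## A worked miniature

```{r example, eval = FALSE}
cfg <- protocol_config("ant", frame_rate = 10, duration_s = 300)
dat <- simulate_tandem_dataset(cfg, n_pairs = 6, seed = 1)

report <- dat |>
  te_report(
    configs = tibble::tibble(pattern = c("rotation", "pausing"),
                             period_s = 0.5, k = 3),
    n_surrogates = 50, seed = 2
  )
report$te_stats[, c("pattern", "net_bits", "dominant_direction")]
```

The rotation row comes out with positive net TE (leader to follower) and
the pausing row negative (follower to leader): the two concurrent,
oppositely-directed channels that distinguish the acknowledgment protocol
from simple leading.
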