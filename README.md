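# tandemflow

Information-flow analysis of leader–follower tandem running.

During a tandem run, a leader insect guides a follower along a route while
the follower keeps close contact behind it. Ants and termites perform
outwardly similar tandem runs using similar short-range signals, yet use
them for different purposes (route learning versus mate cohesion). The
difference lives in the *communication protocol* — who predicts whom,
about what, over intermediate time scales — and `tandemflow` measures it
non-invasively from paired movement trajectories. The package is aimed at
behavioral ecologists and anyone doing time-series causal inference on
paired movement data.

## What it computes

Each runner's trajectory is coarse-grained into a symbolic series for one
behavioral channel — turning direction (`CW`/`CCW`), stop-and-go behavior
(`M`/`P`, threshold at a percentile of the bimodal step-size
distribution), or their mutually exclusive combination — and directed
predictive information between leader *L* and follower *F* is estimated
as symbolic transfer entropy with a sparse plug-in estimator:

$$T_{L \to F} = \sum p\!\left(f_{i+1}, f_i^{(k)}, l_i\right)
  \log_2 \frac{p\!\left(f_{i+1} \mid f_i^{(k)}, l_i\right)}
              {p\!\left(f_{i+1} \mid f_i^{(k)}\right)}$$

together with its per-time-step decomposition (local transfer entropy,
which can be negative at misinformative moments), the net flow
$T_{L\to F} - T_{F\to L}$, and the normalized form
$T / H(F_{i+1}\mid F^{(k)})$. Finite-sample bias is corrected against
surrogate datasets built by re-pairing leaders with followers of
*different* trials (derangements), and directionality is tested with
one-sided Wilcoxon rank-sum and signed-rank tests with continuity
correction. A sweep over sampling periods × history lengths (900
configurations by default) selects the analysis scale, and local TE
binned by inter-centroid distance (LOESS-smoothed, span 0.3) shows *where*
each channel carries information. A coupled-walker simulator generates
trajectory pairs under ant-like, termite-like, or independent protocols
with known ground-truth flow directions, so the entire pipeline is
testable without animal recordings.

## Worked example

Simulate six ant-protocol pairs (300 s at 10 Hz), analyse both channels
at a 0.5-s sampling period with history length 3, and ask who predicts
whom:

```r
library(tandemflow)

cfg <- protocol_config("ant", frame_rate = 10, duration_s = 300)
dat <- simulate_tandem_dataset(cfg, n_pairs = 6, seed = 1)

sym <- dat |>
  subsample_trajectories(0.5) |>
  encode_pattern("rotation")
transfer_entropy(sym, "leader", "follower", k = 3)
#> <tandem_te> T[leader->follower] = 0.134535 bits (H(dest future | k=3 history) = 0.877223 bits)
#>   pattern rotation, period 0.5000 s, mode pooled, 3570 transitions

surrogate_te(sym, "leader", "follower", k = 3, n_replicates = 50, seed = 2)
#> <te_surrogates> 50 replicates, T[leader->follower] = 0.001510 +/- 0.000094 bits (k=3, seed 2)
```

The leader's turning carries ~0.13 bits per step about the follower's
next turn beyond the follower's own history (15% of its remaining
uncertainty), while re-paired surrogates carry ~0.0015 bits — the
coupling is real, not estimator bias. The full report over both channels:

```r
rep <- te_report(dat,
                 tibble::tibble(pattern = c("rotation", "pausing"),
                                period_s = 0.5, k = 3),
                 n_surrogates = 50, seed = 2)
rep$te_stats[, c("pattern", "te_lf_bits", "te_fl_bits", "net_bits", "dominant_direction")]
#>    pattern te_lf_bits te_fl_bits net_bits dominant_direction
#> 1 rotation     0.1452    0.00878   0.1338   leader->follower
#> 2  pausing     0.0048    0.02230  -0.0192   follower->leader
```

Rotation information flows leader→follower (the leader steers the route)
while pausing information flows follower→leader (the follower's search
pauses predict the leader's stops) — two concurrent, oppositely directed
channels within one behavior, the signature of an acknowledgment-based
protocol. `rep$tests` carries the matching rank-sum/signed-rank
statistics (e.g. the rotation L→F estimate beats its surrogates at
W = 36, p = 0.0025, with 6 trials).

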