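# tvarnet

Event-locked, time-varying **directed** network analysis for multichannel
EEG — the analysis chain used to study how a single TMS pulse transiently
reorganizes cortical connectivity during attention tasks, packaged for anyone
who needs time-resolved effective connectivity around a repeated event
(TMS pulses, stimuli, or any time-locked marker).

## What it computes

Within each peri-event epoch the data follow a time-varying multivariate
adaptive autoregressive (TV-MVAAR) model

```
X(t) = Σ_{i=1..p} A_i(t) X(t−i) + E(t)
```

whose coefficient matrices `A_i(t)` are tracked with a multi-trial
Kalman filter (all trials share the time-locked nonstationarity, so the
state update at each time point assimilates the whole trial ensemble). From
the fit, the adaptive directed transfer function (ADTF)

```
γ²_ij(f,t) = |H_ij(f,t)|² / Σ_m |H_im(f,t)|²,   H(f,t) = [I − Σ_i A_i(t) e^(−j2πfi/fs)]⁻¹
```

quantifies directed coupling from channel *j* to channel *i* per frequency
and time; band-averaging gives θ_ij(t), and each node's **normalized total
information outflow** is

```
Q_j²(t) = Σ_{k≠j} θ_kj(t) / (n − 1).
```

On top of this, the package provides surrogate-calibrated edge thresholds,
key-node (hub) trajectories with conversion times, enhanced/weakened edge
intervals relative to the pre-event baseline, scalp-region aggregation, and
modularity-based module partitioning — plus a fully ground-truthed
synthetic-data module (nonstationary MVAR simulator, TMS pulse trains,
attention-task digit streams, behavioral logs) that validates every stage.
See the vignette in `vignettes/time-varying-networks.Rmd` for the modelling
choices and their rationale.

## Worked example

Simulate a 10-minute session in which the coupling 1→2 is briefly severed
76–450 ms after each pulse and then overshoots (0.4 → 0 → 0.6), then recover
that pattern from the data alone:

```r
library(tvarnet)

sched <- build_coefficient_schedule(
  4, 1,
  base_edges = data.frame(source = c(1, 2, 3, 4, 1), sink = c(1, 2, 3, 4, 2),
                          lag = 1, weight = c(0.5, 0.5, 0.5, 0.5, 0.4)),
  perturbations = data.frame(source = 1, sink = 2, lag = 1,
                             weight = c(0, 0.6),
                             start = c(0.076, 0.45), end = c(0.45, 1.0)),
  t_start = -0.5, t_end = 1)

events <- place_tms_events(600, 4, 2)            # one pulse every 4 s
rec <- simulate_session(sched, fs = 256, duration = 600, events = events,
                        seed = 1)
epochs <- extract_epochs(rec, events, pre = 0.5, post = 1.0) |>
  decimate_epochs(32)                            # 48 samples per 1.5-s epoch
epochs
#> <eeg_epochs> 150 trials x 4 channels x 48 samples @ 32 Hz, t in [-0.5, 0.9688] s

fit <- fit_tvmvar(epochs, order = 1, uc = 0.01)
ba  <- integrate_band(adtf_normalize(transfer_function(fit)), band = c(1, 15))

dplyr::filter(classify_edge_dynamics(ba), source == "Fp1", sink == "Fp2")
#> # A tibble: 2 × 6
#>   source sink  class    onset_s offset_s effect_size
#>   <chr>  <chr> <chr>      <dbl>    <dbl>       <dbl>
#> 1 Fp1    Fp2   weakened  0.0938      0.5     -0.0676
#> 2 Fp1    Fp2   enhanced  0.531       1        0.155
```

The classifier recovers the planted sequence: a weakened interval with onset
93.8 ms (ground truth 76 ms; the forward-only filter lags by about one
32-Hz sample) and an enhanced interval from ~0.53 s (ground truth 0.45 s),
with effect sizes of the right sign. Node outflow and modules come from the
same band-integrated tensor:

```r
head(total_outflow(ba), 4)
#> # A tibble: 4 × 3
#>   time_s node  outflow
#>    <dbl> <chr>   <dbl>
#> 1 -0.469 Fp1   0.0316
#> 2 -0.469 Fp2   0.0447
#> 3 -0.469 F7    0.0117
#> 4 -0.469 F3    0.00809

detect_modules(ba, window = c(0, 0.97))
#> <module_partition> 2 module(s), Q_mod = 0.0711
```

Every result type has `tidy()`/`glance()` methods and an `autoplot()`; the
whole chain (including surrogate thresholds and key-node trajectories) runs
as one call via `run_pipeline(pipeline_config(...))`, and a thin CLI lives in
`inst/cli/tvarnet.R` (`simulate`, `run`, `behavior`, `report`).

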