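# ankleguard

Adaptive ensemble sizing for real-time ankle-injury risk detection from
wearable inertial (IMU) streams.

Ankle sprains are typically preceded by a few hundred milliseconds of
kinematic drift. A wearable detector that wants to catch that drift in real
time has to balance detection accuracy against the latency and energy budget
of an embedded CPU. `ankleguard` implements an adaptive detector for this
setting, aimed at researchers in wearable-sensor biomechanics and
sports-injury informatics:

* a **hybrid temporal ensemble**: an int8-quantized depthwise-separable 1D
  CNN (kernels 5/3/3, channels 32→64→128, stride 2) fused with a
  magnitude-pruned two-layer LSTM (64/32 hidden units) through a mixing
  coefficient α:
  ŷ_t = α_t · softmax(W_c h_CNN) + (1 − α_t) · softmax(W_l h_LSTM);
* a **Gaussian-process motion forecaster** with composite kernel
  k = σ_f² Matérn₃,₂ + σ_p² Periodic (σ_f² = 1.24, σ_p² = 0.58), a
  50-observation sliding buffer and a sigmoid risk head predicting the risk
  score r at a 150 ms horizon;
* a **Q-learning controller** (two-layer swish Q-network, ε-greedy 0.1→0.01
  over 1,000 steps, 10,000-transition circular replay) that picks (α_t, β_t)
  — the mixing coefficient and the LSTM pruning ratio — each window from the
  four-term reward R = λ₁·Acc − λ₂·Latency − λ₃·Energy + λ₄·𝟙(r > 0.6);
* a **seeded synthetic motion generator** covering six athletic scenarios
  (steady running, directional changes, jump landings, collisions, fatigue
  degradation, sensor dropout), four injury categories at a realistic
  62.5/16.8/12.6/8.0 % split with pre-injury kinematic drift;
* the full **preprocessing chain** (calibration, 20 Hz zero-phase
  Butterworth, complementary-filter gravity removal, 200 Hz resampling,
  200 ms / 50 % windows, subject-level splits, SMOTE + class weights) and
  the **lead-time metric suite** (IDA, FAR, APA@150 ms, adaptation
  overhead, paired t-tests, risk–outcome correlation, accuracy–latency
  sweeps).

Everything is tibble-in / tibble-out and pipe-friendly, with broom-style
`tidy()`/`glance()` and `ggplot2::autoplot()` methods.

## Worked example

```r
library(ankleguard)

# one simulated 30 s session at 200 Hz with labeled injury events
s <- generate_session(duration_s = 30, seed = 7)
s
#> <imu_stream> 6000 samples @ 200 Hz (30.0 s), 6 channels, 7 segments, 9 events, 0 dropout intervals

# the whole pipeline on a small cohort (simulate -> preprocess -> train ->
# run all ablation modes -> evaluate), checkpointed under out_dir
cfg <- validate_config(list(
  simulation = list(n_subjects = 5L, duration_s = 30),
  models = list(max_epochs = 4L, patience = 2L)))
man <- run_end_to_end(cfg, out_dir = tempfile("ankleguard-"))
man
#> <run_manifest> 249c5e02158c411cefaef620a0f27af5 (seed 1)
#>   full           IDA 100.0%  FAR  82.9%  APA  75.0%
#>   no_rl          IDA 100.0%  FAR  20.0%  APA  25.0%
#>   no_gp          IDA 100.0%  FAR  81.8%  APA  75.0%
#>   no_dyn_prune   IDA 100.0%  FAR  82.5%  APA 100.0%
#>   fixed_ensemble IDA 100.0%  FAR  20.0%  APA  25.0%
```

Reading the output: IDA (injury detection accuracy) is the percentage of
injury events in the held-out test session that received an alert inside the
match window; FAR (false alarm rate) the percentage of alert episodes not
matched to any event; APA@150 ms the percentage of events alerted at least
150 ms in advance. On this small synthetic cohort the injected pre-injury
drift is strong, so every mode detects all events, and the adaptive modes
(which classify more aggressively here) earn a large advance-prediction
margin over the frozen `fixed_ensemble` (α = 0.5, β = 0.4). The demo's
held-out split is a single session, so its FAR column is dominated by a
handful of alert episodes; the seeded 10-session benchmark in the
acceptance suite is the calibrated comparison, where the full system
matches the fixed ensemble on IDA and undercuts it on FAR.

Individual pieces compose with the pipe:

```r
w <- generate_session(30, seed = 1) |> preprocess_stream()
stats <- compute_norm_stats(w)           # training split only
wn <- z_normalize(w, stats)
glance(man$models$lstm_fit)
#> # A tibble: 1 × 5
#>   branch epochs best_val_loss prune_ratio sparsity
#>   <chr>   <int>         <dbl>       <dbl>    <dbl>
#> 1 lstm        4         0.746         0.4    0.400
autoplot(man$models$agent)    # learning curve
```

A thin CLI over the same functions is installed at
`system.file("cli/ankleguard", package = "ankleguard")` with subcommands
`simulate`, `preprocess`, `train`, `run --mode`, `evaluate`,
`sweep-tradeoff` and `demo`.

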