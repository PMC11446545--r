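# mudecomp

Real-time decoding of motor unit activity from multichannel EMG.

The discharge timing of spinal motor neurons can be read out non-invasively
(or minimally invasively) by decomposing multichannel electromyographic
signals into motor unit spike trains. During stationary (isometric)
contractions, the recording is a convolutive mixture

> X(t) = Σ<sub>l=0..L−1</sub> H(l) S(t − l) + N(t)

of delta-function spike trains S with per-channel action potential shapes H
of duration L. `mudecomp` implements the two-stage interface used for motor
unit neurofeedback:

1. **Calibration** — on a baseline contraction, signal extension (R ≈ 1000/m
   delayed copies), whitening, and fixed-point ICA with deflation estimate
   one *separation vector* (motor unit filter) per source; peak detection,
   two-class k-means (spike vs noise), spike-triggered refinement that
   minimises the CoV of the interspike intervals, a silhouette gate
   (SIL ≥ 0.90) and duplicate removal decide which motor units are kept.
2. **Real time** — the frozen filters, whitening and spike/noise centroids
   are re-applied to streamed 125-ms epochs; local maxima ≥ 25 ms apart are
   classified by nearest centroid; smoothed firing rates (spike count over
   the trailing second, averaged over the last four values) feed raster /
   quadrant / rate-path visual feedback.

The package also ships a motor-unit-pool EMG simulator with ground-truth
discharge times (recruitment thresholds over a 30-fold range, rate coding,
twitch-force superposition under a PID force controller, surrogate
multichannel action potentials for a 13×5 surface grid at 2048 Hz and a
16-electrode intramuscular array at 10,240 Hz), a programmatic spike-train
editor, and agreement metrics (rate of agreement TP/(TP+FN+FP), sensitivity,
precision, false-negative rate, smoothed-rate RMSE).

It is written for neurophysiologists and neural-interface engineers who
want an inspectable, scriptable counterpart to GUI decomposition tools:
tabular results are tibbles, fitted objects have `tidy()` / `glance()` /
`autoplot()` methods, and every stage is a plain function.

## Worked example

Simulate a 20% MVC trapezoidal baseline on the intramuscular array,
calibrate filters, and stream a sinusoidal test contraction through them:

```r
library(mudecomp)

pool <- build_motor_unit_pool(150, seed = 11)
arr  <- electrode_array("intramuscular_array")
tmpl <- synthesize_muap_templates(pool, array = arr, seed = 12)

baseline <- render_emg(
  simulate_contraction(pool, generate_force_profile("trapezoid", 10240,
                       ramp_duration = 2, plateau_duration = 8,
                       plateau_level = 20), seed = 21),
  tmpl, seed = 22)

dec <- decompose_offline(baseline,
         mu_config(decomposition = list(n_sources = 10, max_iter = 60)),
         seed = 1)
dec
#> <mu_decomposition> 9 accepted motor units (1 candidates rejected)
#>   SIL 0.929-0.991, extension R = 62, 735 whitened dims

tidy(dec)[1:3, 1:5]
#> # A tibble: 3 x 5
#>    unit   sil cov_isi n_spikes mean_rate_pps
#>   <int> <dbl>   <dbl>    <int>         <dbl>
#> 1     1 0.978   0.179      116          11.7
#> 2     2 0.990   0.171      108          11.4
#> 3     3 0.991   0.147       94          10.3
```

Each accepted unit carries its filter, spike/noise centroids and silhouette.
`sil` is the normalised spike/noise separation (≈ 0.95 for well-isolated
units), `cov_isi` the discharge regularity (≈ 0.15–0.25 during steady
force), and `mean_rate_pps` the mean firing rate. Now stream a different
contraction — a 15–25% MVC sinusoid — through the frozen filters, epoch by
epoch, and score the real-time output against the simulator's ground truth:

```r
test_truth <- simulate_contraction(pool,
  generate_force_profile("sinusoid", 10240, duration = 12), seed = 31)
test <- render_emg(test_truth, tmpl, seed = 32)

res <- stream_recording(test, dec)
res
#> <stream_result> 96 epochs, 9 units, 1299 discharges

sc <- score_against_truth(res$spike_trains, test_truth)
dplyr::summarise(sc, mean_roa = mean(roa), mean_precision = mean(precision))
#> # A tibble: 1 x 2
#>   mean_roa mean_precision
#>      <dbl>          <dbl>
#> 1    0.974          0.983
```

A mean rate of agreement of 0.974 means that, per motor unit, 97% of the
discharges identified in real time coincide (within ±0.5 ms, after constant
delay removal) with the simulated ground truth of a contraction pattern the
filters never saw. Visualise with `autoplot(res)` (smoothed rates) and
`autoplot(dec)` (discharge raster).

A thin command-line interface wraps the same functions
(`inst/cli/mu-decomp`): `simulate`, `decompose`, `stream`, `evaluate`,
`fixture`, each with `--seed`, `--config` (YAML) and `--out`, writing
portable containers (Arrow + JSON), CSV discharges and JSON score reports.

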