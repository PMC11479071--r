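# pulsebeam

Non-contact heart-rate-variability (HRV) analysis from impulse-radio
ultra-wideband (IR-UWB) radar recordings, in R.

An IR-UWB radar pointed at a seated person records a complex matrix per
evaluation: fast time (pulse time-of-arrival, hence range, ~6.4 mm per bin)
by slow time (250 frames per second). The chest modulates the phase of the
return at the subject's range by `4π d(t)/λ` — millimetres of respiration
and tenths of a millimetre per heartbeat. pulsebeam turns that matrix into
beat-to-beat RR intervals and standard HRV indices, and provides the
statistical machinery to validate the radar against a contact reference and
to test HRV indices as markers of self-reported psychological distress:

- **Preprocessing** — reference-bin phase compensation (cancels frame-common
  phase jitter exactly) and linear-phase FIR band-pass filtering of the
  slow-time axis with group-delay removal.
- **Movement detection** — per-second frame-difference statistic with a
  trimmed-mean CFAR threshold; flagged seconds exclude the RR intervals they
  touch.
- **Vital-point selection** — ranks fast-time bins by heart-band
  (40/60–130/60 Hz) spectral power over the bin's own noise floor, then
  demodulates the winning bin (phase unwrapping by default).
- **Peak detection** — amplitude-ordered iterative argmax with ±R
  suppression and window-max validation; R defaults to half the fastest
  plausible beat spacing (57 frames at 250 FPS, 130 bpm ceiling).
- **HRV indices** — mean RR, SDNN, RMSSD; LF/HF from a Hamming-windowed,
  zero-padded FFT of the RR sequence mapped to Hz by the effective beat rate.
- **Agreement statistics** — outlier screening, Pearson r, Bland–Altman
  limits of agreement, ICC(2,1) with F-based confidence interval.
- **Distress analysis** — VAS grouping (0–10 at 2.5-wide bins), two-group
  ANOVA, ROC with a priori index orientation and top-left optimal threshold.
- **Synthetic scene simulator** — radar cubes and study tables with known
  ground truth (displacement model, direct path, phase jitter, noise,
  movement bursts), so every stage is testable without hardware or human
  data.

Tabular results are tibbles; report objects support `tidy()`, `glance()`,
and `autoplot()`.

## Worked example

Simulate one clean 5-minute evaluation and recover its HRV:

```r
library(pulsebeam)

sp    <- scene_params(snr_db = 60, phase_jitter_sd_rad = 0, seed = 1)
truth <- generate_rr_series(sp, 300)
scene <- render_cube(truth, sp, acquisition_config())
hrv   <- evaluate_hrv(scene$cube)
hrv
#> # A tibble: 1 × 10
#>   mean_rr_ms sdnn_ms rmssd_ms     lf_power     hf_power lf_hf_ratio n_intervals
#>        <dbl>   <dbl>    <dbl>        <dbl>        <dbl>       <dbl>       <int>
#> 1       801.    39.8     49.2 10424286434. 12294074802.       0.848         364
#>   movement_s n_peaks mp_bin
#>        <int>   <int>  <int>
#> 1          0     365     47

c(mean(truth$rr_true_ms), sd(truth$rr_true_ms))
#> [1] 800.17  40.10
```

The pipeline selected fast-time bin 47 — exactly the bin at the simulated
0.7 m subject range — found 365 beats, and recovered the mean RR within
0.5 ms and SDNN within 1% of truth.

Generate a synthetic 102-evaluation study, screen outliers, and run the
agreement and distress analyses:

```r
study <- apply_outlier_rules(generate_study(study_params(seed = 6)))
sum(study$valid)
#> [1] 98

tidy(agreement_report(study))
#> # A tibble: 4 × 10
#>   index       n pearson_r   p_value    bias loa_low loa_high   icc icc_ci_low icc_ci_high
#>   <chr>   <int>     <dbl>     <dbl>   <dbl>   <dbl>    <dbl> <dbl>      <dbl>       <dbl>
#> 1 mean_rr    98     1.000 4.10e-155 -0.397   -4.95     4.16  1.000      1.000       1.000
#> 2 sdnn       98     0.946 8.81e- 49  0.171  -10.6     10.9   0.946      0.921       0.964
#> 3 rmssd      98     0.697 1.56e- 15 -1.58   -37.5     34.3   0.667      0.541       0.764
#> 4 lf_hf      98     0.763 6.68e- 20  0.0272  -0.475    0.529 0.698      0.581       0.787

tidy(distress_report(study))
#> # A tibble: 4 × 9
#>   index          f        p mean_low mean_high   auc threshold sensitivity specificity
#>   <chr>      <dbl>    <dbl>    <dbl>     <dbl> <dbl>     <dbl>       <dbl>       <dbl>
#> 1 mean_rr 16.4     0.000323  859.      727.    0.772   753.          0.75        0.711
#> 2 sdnn     4.05    0.0530     36.0      25.2   0.740    27.9         0.75        0.7
#> 3 rmssd   0.00260  0.960      50.0      50.6   0.517    56.1         0.667       0.522
#> 4 lf_hf   4.03     0.0535      0.572     0.906 0.696     0.864       0.583       0.756
```

The full pipeline (both tiers, configurable via a single JSON config with
unknown-key rejection) runs with:

```r
res <- run_pipeline(demo_config(seed = 1), out_dir = "artifacts")
```

or from the shell:

```sh
exec/pulsebeam demo --seed 1 --out artifacts
exec/pulsebeam run --config my_config.json --out artifacts
```

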