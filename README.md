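# xenocall

Kinematic–acoustic analysis of underwater sound production in clawed frogs
(*Xenopus*).

Male *Xenopus* call underwater without airflow: each sound pulse arises
when the paired arytenoid discs of the larynx, held together by a capillary
liquid bridge, are rapidly pulled apart by muscle contraction. `xenocall`
implements the two analyses that establish and characterise this mechanism,
for researchers working with high-speed laryngeal video and bioacoustic
recordings:

1. **Mechanism pipeline** — subpixel tracking of disc markers in high-speed
   video by normalized cross-correlation (quadratic peak interpolation),
   gap-width kinematics w(t) with velocity and acceleration from smoothed
   central differences, zero-phase 1–4 kHz band-pass conditioning of the
   sound trace, per-stimulus onset detection at a 0.01 Pa threshold,
   onset-lag statistics, OLS regressions of pulse amplitude (mPa) on peak
   velocity (mm/s) and acceleration (g) with the motion threshold taken as
   the regression x-intercept, and a cavitation-consistency diagnostic
   (observed mPa/ms pulses vs the ~50–100 kPa/µs signature of bubble
   collapse).
2. **Dyad pipeline** — envelope-based pulse segmentation with attack
   exclusion, Hann-windowed zero-padded power spectra, extraction of the
   two dominant frequencies (DF1 < DF2) with parabolic interpolation,
   Q-values from the −6 dB bandwidth, the DF2/DF1 ratio, and its
   musical-interval class: the ratio is assigned the nearest of
   2:1 (Octave), 3:2 (Perfect 5th), 4:3 (Perfect 4th), 5:4 (Major Third),
   6:5 (Minor Third) when within 2 % of it, else "Non-consonant".
   Species summaries are means of per-male means; clade-band means use an
   editable clade configuration.

Because no raw recordings accompany the study, a first-class synthetic-data
module (`gen_disc_trajectory`, `render_bead_frames`, `synth_pulse_sound`,
`synth_advertisement_call`) generates video, audio and paired experiments
with closed-form ground truth — logistic gap openings with analytic
`v_peak = k·gap_max/4` and `a_peak = k²·gap_max/(6√3)`, facilitation ramps,
threshold-gated pulses with amplitude `min(5.2·v − 210.5, 180)` mPa, and
biphasic trills — so every stage is testable without any download.

## Worked example

```r
library(xenocall)

## mechanism: simulate one ex vivo experiment and analyse it
train <- stimulus_train(rate_hz = 40, count = 40, t_first = 0.1)
ex  <- gen_disc_trajectory(disc_motion_params(), train, frame_rate = 40000, seed = 1)
snd <- synth_pulse_sound(ex$truth, pulse_sound_params(), sample_rate = 30000, seed = 2,
                         duration_s = max(ex$truth$t_s) + 0.02)

ks  <- differentiate_series(compute_gap_width(ex$left, ex$right, rest_frames = 1:2000),
                            smooth_window = 13)
kev <- kinematic_events(ks, train)
sev <- detect_onsets(bandpass(snd), train, threshold_pa = 0.01)
ce  <- join_events(kev, sev)

round(mean(ce$lag_onset_vpeak_ms, na.rm = TRUE), 2)  # onset after peak velocity (ms)
#> [1] 0.5
regress_amplitude(ce, "v_peak")
#> Amplitude regression (ptp mPa ~ v_peak, n = 33)
#>   y = 5.46 x -223.0, R^2 = 0.987
#>   motion threshold (x-intercept): 40.83; min sounded: 46.38
print(cavitation_check(ce, pulse_dur_ms = 5))
#> Cavitation-consistency diagnostic
#>   max ptp: 0.0946 Pa vs reference 5e+04-1e+05 Pa -> 5.28e+05-fold too low: inconsistent
#>   pulse duration: 5 ms vs 1e-06 s -> 5e+03-fold too slow: inconsistent
#>   verdict: inconsistent with cavitation
```

The simulated experiment was generated with an onset lag of 0.51 ms, an
amplitude line of slope 5.2 mPa/(mm/s) and a velocity threshold of
40.5 mm/s; the pipeline recovers 0.50 ms, 5.46 (within the fit's 95 % CI)
and 40.8 mm/s from the raw traces, and the diagnostic rejects cavitation by
more than three orders of magnitude on both the pressure and time axes.

```r
## dyads: measure a synthetic X. borealis pulse
cs  <- call_spec(1253, 2504, n_fast = 1, n_slow = 0, pulse_rate_fast = 1,
                 pulse_dur_ms = 500, decay = 4)
trc <- synth_advertisement_call(cs, seed = 11)
m   <- measure_dyad(segment_pulses(trc, attack_ms = 2)[[1]])
m[, c("df1_hz", "df2_hz", "ratio_2dp", "interval")]
#>   df1_hz df2_hz ratio_2dp interval
#> 1   1253   2504         2   Octave
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic
fixtures and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # video (TIFF), audio (WAV), truth (CSV)
Rscript analysis/02_track_kinematics.R  # tracking + kinematics vs ground truth
Rscript analysis/03_mechanism.R         # onsets, lags, regressions, cavitation report
Rscript analysis/04_dyads_table1.R      # per-species dyad table + clade means
```

Each stage reads the files the previous one wrote (multi-page TIFF, WAV,
CSV, YAML config echo), so any stage can be pointed at real recordings in
the same formats.

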