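#' Disc-motion generator parameters
#'
#' Parameters of the synthetic arytenoid-disc gap profile. Each nerve stimulus
#' opens the gap along a logistic rise of amplitude `gap_max_um` and steepness
#' `steepness` (1/s), followed, after `hold_s`, by a slower logistic closure
#' back to rest. The logistic has closed-form kinematics:
#' peak opening velocity `gap_max * steepness / 4` and peak opening
#' acceleration `gap_max * steepness^2 / (6 * sqrt(3))`, which anchor the
#' generator's ground truth.
#'
#' Neuromuscular facilitation is modelled as a multiplicative ramp on the
#' per-stimulus gap amplitude, `scale_i = 1 - exp(-i / facil_tau)`, with
#' optional lognormal jitter (`scale_jitter_sd`, relative SD). With the
#' defaults the first stimulus stays below the sound-production velocity
#' threshold and the second barely crosses it, so the first pulse detectable
#' above the 0.01 Pa onset threshold typically falls on stimulus 3, as
#' observed ex vivo.
#'
#' Defaults reproduce the reported ex vivo disc kinematics regime
#' (peak velocity 50.3 mm/s, peak acceleration 13.5 g with 1 g = 9.82 m/s^2);
#' a single logistic has two degrees of freedom, so `gap_max_um` and
#' `steepness` follow from those two peaks.
#'
#' @param gap_max_um asymptotic gap opening per stimulus, micrometres.
#' @param steepness logistic rate constant k, 1/s.
#' @param t_open_s delay from stimulus onset to the logistic midpoint, s.
#' @param hold_s delay from the opening midpoint to the closure midpoint, s.
#' @param close_steepness rate constant of the closing logistic, 1/s; keep
#'   well below `steepness` so closure does not contaminate opening peaks.
#' @param rest_jitter_um SD of Gaussian positional jitter added to the true
#'   bead tracks, micrometres.
#' @param facil_tau facilitation time constant in units of stimuli.
#' @param scale_jitter_sd relative SD of per-stimulus amplitude jitter.
#' @param rest_separation_um bead separation at rest, micrometres.
#' @return An object of class `disc_motion_params`.
#' @export
disc_motion_params <- function(gap_max_um = 29.38,
                               steepness = 6847,
                               t_open_s = 2.5e-3,
                               hold_s = 4e-3,
                               close_steepness = 2000,
                               rest_jitter_um = 0.05,
                               facil_tau = 1.2,
                               scale_jitter_sd = 0.10,
                               rest_separation_um = 150) {
  stopifnot(gap_max_um >= 0, steepness > 0, close_steepness > 0,
            hold_s > 0, rest_jitter_um >= 0, facil_tau > 0,
            scale_jitter_sd >= 0, rest_separation_um > 0)
  structure(list(gap_max_um = gap_max_um, steepness = steepness,
                 t_open_s = t_open_s, hold_s = hold_s,
                 close_steepness = close_steepness,
                 rest_jitter_um = rest_jitter_um,
                 facil_tau = facil_tau, scale_jitter_sd = scale_jitter_sd,
                 rest_separation_um = rest_separation_um),
            class = "disc_motion_params")
}

#' Pulse-sound generator parameters
#'
#' Parameters of the synthetic per-stimulus sound pulse. A stimulus whose peak
#' disc velocity exceeds `v_threshold_mm_s` emits a damped two-tone pulse
#' (components `df1_hz`, `df2_hz`, amplitude decay `decay` 1/s) preceded by a
#' short broadband attack, starting `lag_onset_s` after the instant of peak
#' disc velocity. Its peak-to-peak amplitude follows the line
#' `amp_intercept_mpa + amp_slope * v_peak` (mPa vs mm/s) clipped at
#' `ptp_saturation_mpa`. Defaults take the reported ex vivo regression
#' (slope 5.2, intercept -210.5, saturation ~180 mPa) and onset lag
#' (0.51 ms after peak velocity); the default velocity threshold is the
#' x-intercept of that line, 210.5/5.2 = 40.5 mm/s.
#'
#' @param df1_hz,df2_hz lower and higher dominant frequency, Hz (`df1 < df2`).
#' @param amp2 amplitude of the df2 component relative to df1.
#' @param decay exponential amplitude decay rate of the tonal part, 1/s.
#' @param attack_ms duration of the broadband attack segment, ms.
#' @param attack_gain attack amplitude relative to the tonal peak.
#' @param lag_onset_s sound onset lag after peak disc velocity, s.
#' @param amp_slope regression slope, mPa per mm/s.
#' @param amp_intercept_mpa regression intercept, mPa.
#' @param v_threshold_mm_s minimal peak velocity for sound emission, mm/s.
#' @param ptp_saturation_mpa peak-to-peak amplitude ceiling, mPa.
#' @param noise_sd_pa SD of additive Gaussian background noise, Pa.
#' @return An object of class `pulse_sound_params`.
#' @export
pulse_sound_params <- function(df1_hz = 1879,
                               df2_hz = 2154,
                               amp2 = 1,
                               decay = 600,
                               attack_ms = 1.5,
                               attack_gain = 0.5,
                               lag_onset_s = 0.51e-3,
                               amp_slope = 5.2,
                               amp_intercept_mpa = -210.5,
                               v_threshold_mm_s = 210.5 / 5.2,
                               ptp_saturation_mpa = 180,
                               noise_sd_pa = 0.002) {
  stopifnot(df1_hz > 0, df2_hz > df1_hz, decay > 0, attack_ms >= 0,
            attack_gain >= 0, lag_onset_s >= 0, ptp_saturation_mpa > 0,
            noise_sd_pa >= 0)
  structure(list(df1_hz = df1_hz, df2_hz = df2_hz, amp2 = amp2,
                 decay = decay, attack_ms = attack_ms,
                 attack_gain = attack_gain, lag_onset_s = lag_onset_s,
                 amp_slope = amp_slope, amp_intercept_mpa = amp_intercept_mpa,
                 v_threshold_mm_s = v_threshold_mm_s,
                 ptp_saturation_mpa = ptp_saturation_mpa,
                 noise_sd_pa = noise_sd_pa),
            class = "pulse_sound_params")
}

#' Advertisement-call specification
#'
#' Specification of a synthetic male advertisement call: a biphasic pulse
#' train (fast trill then slow trill) in which every pulse carries a broadband
#' attack followed by a sustained two-tone dyad at `df1_hz`/`df2_hz`.
#' Defaults emulate the typical trill rates (~60 and ~30 pulses/s).
#'
#' @param df1_hz,df2_hz dominant frequencies, Hz; `df2_hz` may equal 0 to
#'   emit a single-band call (the punctured-septa degenerate case is obtained
#'   with `amp2 = 0`).
#' @param amp2 amplitude of the df2 component relative to df1; 0 gives a
#'   single-band call.
#' @param pulse_rate_fast,pulse_rate_slow trill rates, pulses/s.
#' @param n_fast,n_slow pulse counts in the fast and slow trill; set
#'   `n_slow = 0` for a single trill.
#' @param pulse_dur_ms sound-pulse duration, ms; must satisfy
#'   `pulse_dur_ms * rate < 1000` so pulses do not overlap.
#' @param decay tonal amplitude decay within a pulse, 1/s.
#' @param attack_ms,attack_gain broadband attack duration (ms) and relative
#'   amplitude.
#' @param amp_pa peak amplitude of the tonal part, Pa.
#' @param noise_sd_pa SD of additive background noise, Pa.
#' @param sample_rate audio sample rate, Hz.
#' @return An object of class `call_spec`.
#' @export
call_spec <- function(df1_hz, df2_hz, amp2 = 1,
                      pulse_rate_fast = 60, pulse_rate_slow = 30,
                      n_fast = 60, n_slow = 30,
                      pulse_dur_ms = 8, decay = 250,
                      attack_ms = 1.5, attack_gain = 0.5,
                      amp_pa = 0.1, noise_sd_pa = 1e-4,
                      sample_rate = 44100) {
  stopifnot(df1_hz > 0, pulse_rate_fast > 0, pulse_rate_slow > 0,
            n_fast >= 0, n_slow >= 0, n_fast + n_slow >= 1,
            pulse_dur_ms > 0, amp_pa > 0, sample_rate > 0)
  if (amp2 > 0 && df2_hz <= df1_hz)
    stop("df2_hz must exceed df1_hz when a second component is present")
  if (pulse_dur_ms * pulse_rate_fast >= 1000 ||
      (n_slow > 0 && pulse_dur_ms * pulse_rate_slow >= 1000))
    stop("pulses would overlap: pulse_dur_ms * rate must stay below 1000")
  if (sample_rate < 4 * max(df1_hz, df2_hz))
    stop("sample_rate must be at least 4x the highest dominant frequency")
  structure(list(df1_hz = df1_hz, df2_hz = df2_hz, amp2 = amp2,
                 pulse_rate_fast = pulse_rate_fast,
                 pulse_rate_slow = pulse_rate_slow,
                 n_fast = n_fast, n_slow = n_slow,
                 pulse_dur_ms = pulse_dur_ms, decay = decay,
                 attack_ms = attack_ms, attack_gain = attack_gain,
                 amp_pa = amp_pa, noise_sd_pa = noise_sd_pa,
                 sample_rate = sample_rate),
            class = "call_spec")
}

#' Stimulus train
#'
#' Onset times of a regular nerve-stimulation train (e.g. 40 Hz for 50
#' cycles in the ex vivo preparation).
#'
#' @param rate_hz stimulation rate, Hz.
#' @param count number of stimuli.
#' @param t_first time of the first stimulus, s.
#' @return An object of class `stimulus_train` with fields `onsets` (s),
#'   `rate_hz` and `count`.
#' @export
stimulus_train <- function(rate_hz = 40, count = 40, t_first = 0.1) {
  stopifnot(rate_hz > 0, count >= 1, t_first >= 0)
  structure(list(onsets = t_first + (seq_len(count) - 1) / rate_hz,
                 rate_hz = rate_hz, count = count),
            class = "stimulus_train")
}

#' Published species-level dyad table
#'
#' Species means (with standard errors) of the lower (DF1) and higher (DF2)
#' dominant frequency, their Q-values, the DF2/DF1 ratio and the assigned
#' musical interval for 20 Xenopus species/populations, together with the
#' clade each belongs to (A, L or M). `in_band` marks the species whose
#' ratios constitute the clade-typical bands: the harmonic-stack species
#' (X. allofraseri) and the ratio exceptions (X. wittei, X. largeni,
#' X. laevis South Africa) are excluded from band means. Membership is plain
#' data and can be edited before passing the table to downstream summaries.
#'
#' @return A data.frame with one row per species.
#' @export
xenopus_table1 <- function() {
  df <- data.frame(
    species = c("X. pygmaeus", "X. ruwenzoriensis", "X. amieti",
                "X. boumbaensis", "X. allofraseri", "X. andrei",
                "X. itombwensis", "X. wittei", "X. vestitus",
                "X. lenduensis", "X. largeni", "X. gilli", "X. poweri",
                "X. laevis Nigeria", "X. victorianus", "X. petersii",
                "X. laevis Malawi", "X. laevis South Africa",
                "X. borealis", "X. muelleri"),
    clade = c("A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A",
              "L", "L", "L", "L", "L", "L", "L", "M", "M"),
    n_males = c(3, 1, 3, 3, 1, 3, 3, 3, 2, 3, 2, 3, 3, 3, 3, 3, 3, 3, 3, 2),
    df1_hz = c(1591, 1937, 2043, 2475, NA, 2062, 1179, 1319, 1609, 1595,
               929, 2114, 1714, 2029, 1891, 2124, 1482, 1879, 1253, 1107),
    df1_se = c(40, NA, 107, 16, NA, 30, 32, 35, 2, 28, 45, 45, 28, 17, 78,
               24, 80, 21, 5, 29),
    q1 = c(16.6, 21.6, 22.4, 27.6, NA, 20.8, 12.4, 13.9, 17.7, 17.4, 10.0,
           22.7, 19.1, 22.5, 21.3, 23.6, 15.8, 16.0, 13.9, 12.2),
    df2_hz = c(2124, 2575, 2715, 3291, NA, 2759, 1573, 1545, 2150, 2131,
               1387, 2641, 2159, 2481, 2295, 2576, 1831, 2154, 2504, 2262),
    df2_se = c(54, NA, 152, 29, NA, 51, 38, 38, 2, 33, 59, 62, 38, 22, 102,
               22, 75, 9, 11, 23),
    q2 = c(18.1, 27.8, 27.2, 33.9, NA, 26.7, 15.3, 15.0, 23.3, 22.8, 14.7,
           28.7, 22.7, 26.6, 22.4, 27.7, 17.3, 18.9, 27.8, 16.0),
    ratio = c(1.34, 1.33, 1.33, 1.33, NA, 1.34, 1.33, 1.17, 1.34, 1.34,
              1.49, 1.25, 1.26, 1.22, 1.21, 1.21, 1.24, 1.15, 2.00, 2.04),
    interval = c("Perfect 4th", "Perfect 4th", "Perfect 4th", "Perfect 4th",
                 "Harmonic stack", "Perfect 4th", "Perfect 4th",
                 "Non-consonant", "Perfect 4th", "Perfect 4th",
                 "Perfect 5th", "Major Third", "Major Third", "Minor Third",
                 "Minor Third", "Minor Third", "Major Third",
                 "Non-consonant", "Octave", "Octave"),
    stringsAsFactors = FALSE)
  df$in_band <- !(df$species %in% c("X. allofraseri", "X. wittei",
                                    "X. largeni", "X. laevis South Africa"))
  df
}

#' Clade-level mean dyad ratios
#'
#' Mean of the per-species DF2/DF1 ratios over the members of each clade
#' band. Species flagged `in_band = FALSE` (harmonic stack and ratio
#' exceptions) are excluded.
#'
#' @param table species table in the shape of [xenopus_table1()].
#' @param digits rounding applied to the reported means (2 matches the
#'   published precision); `NULL` for full precision.
#' @return A data.frame with `clade`, `n_species`, `mean_ratio`, `se_ratio`.
#' @export
clade_ratio_means <- function(table = xenopus_table1(), digits = 2) {
  tb <- table[table$in_band & !is.na(table$ratio), ]
  out <- do.call(rbind, lapply(split(tb, tb$clade), function(d) {
    data.frame(clade = d$clade[1], n_species = nrow(d),
               mean_ratio = mean(d$ratio),
               se_ratio = stats::sd(d$ratio) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(digits)) out$mean_ratio <- round(out$mean_ratio, digits)
  out
}

#' Default analysis configuration
#'
#' All stage parameters in one serializable list, with the published
#' defaults: 1-4 kHz 3rd-order zero-phase band-pass, 67 ms background and a
#' 3 x SD noise floor, 0.01 Pa onset threshold, time-of-flight speed
#' 343 m/s, g = 9.82 m/s^2, Q at -6 dB, interval tolerance 0.02 around the
#' five small-integer candidate ratios. The list is echoed into outputs for
#' provenance and can be written/read with [write_config()]/[read_config()].
#'
#' @param seed integer seed recorded with the configuration.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    filter_low_hz = 1000, filter_high_hz = 4000, filter_order = 3,
    background_span_s = 0.067, noise_floor_mult = 3,
    onset_threshold_pa = 0.01,
    sound_speed_m_s = 343, mic_distance_m = 0.023,
    g_m_s2 = 9.82,
    smooth_window = 5, smooth_order = 2,
    interval_tolerance = 0.02,
    interval_candidates = c(Octave = 2 / 1, `Perfect 5th` = 3 / 2,
                            `Perfect 4th` = 4 / 3, `Major Third` = 5 / 4,
                            `Minor Third` = 6 / 5),
    peak_prominence_db = 6, peak_min_sep_hz = 100,
    attack_exclude_ms = 2,
    cavitation_ref_pa = c(5e4, 1e5), cavitation_ref_dur_s = 1e-6),
    class = "run_config")
}
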