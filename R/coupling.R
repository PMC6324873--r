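#' Join kinematic and sound events by stimulus
#'
#' Outer join on `stim_idx`: every kinematic event appears once, with
#' `sounded = FALSE` where the stimulus produced no detected sound. Onset
#' lags are reported in milliseconds relative to the kinematic peaks.
#'
#' @param kin data.frame from [kinematic_events()].
#' @param snd data.frame from [detect_onsets()] (time-of-flight corrected if
#'   applicable).
#' @return A data.frame of `CoupledEvent` rows: kinematics, `ptp_pa`,
#'   `sounded`, and lags `lag_onset_apeak_ms`, `lag_onset_vpeak_ms`,
#'   `lag_vpeak_apeak_ms`.
#' @export
join_events <- function(kin, snd) {
  if (anyDuplicated(kin$stim_idx) || anyDuplicated(snd$stim_idx))
    stop("duplicate stimulus indices")
  m <- merge(kin, snd, by = "stim_idx", all.x = TRUE)
  m$sounded <- !is.na(m$onset_t)
  m$lag_onset_apeak_ms <- (m$onset_t - m$t_apeak) * 1e3
  m$lag_onset_vpeak_ms <- (m$onset_t - m$t_vpeak) * 1e3
  m$lag_vpeak_apeak_ms <- (m$t_vpeak - m$t_apeak) * 1e3
  m[order(m$stim_idx), ]
}

#' Regress sound amplitude on a kinematic peak
#'
#' Ordinary least squares of per-stimulus peak-to-peak sound pressure (mPa)
#' on peak velocity (mm/s) or peak acceleration (g), using sounded events
#' only — the published procedure for estimating the minimal disc motion
#' associated with sound production. The motion threshold is the regression
#' x-intercept `-intercept / slope`; the smallest sounded predictor value is
#' reported as a secondary statistic.
#'
#' @param events data.frame from [join_events()].
#' @param predictor `"v_peak"` (mm/s) or `"a_peak"` (g).
#' @return A list of class `amplitude_regression`: `slope`, `intercept`,
#'   `r_squared`, `x_intercept` (NA with a flag when the slope is not
#'   positive), `min_sounded`, `n_used`, `predictor`, and the underlying
#'   `lm` fit.
#' @export
regress_amplitude <- function(events, predictor = c("v_peak", "a_peak")) {
  predictor <- match.arg(predictor)
  xcol <- if (predictor == "v_peak") "v_peak_mm_s" else "a_peak_g"
  d <- events[events$sounded, ]
  if (nrow(d) < 3)
    stop("need at least 3 sounded events for the regression (have ",
         nrow(d), ")")
  x <- d[[xcol]]; y <- d$ptp_pa * 1e3  # mPa
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(slope = slope, intercept = intercept,
                 r_squared = summary(fit)$r.squared,
                 x_intercept = if (slope > 0) -intercept / slope else NA,
                 threshold_defined = slope > 0,
                 min_sounded = min(x), n_used = nrow(d),
                 predictor = predictor, fit = fit),
            class = "amplitude_regression")
}

#' @export
print.amplitude_regression <- function(x, ...) {
  cat(sprintf("Amplitude regression (ptp mPa ~ %s, n = %d)\n",
              x$predictor, x$n_used))
  cat(sprintf("  y = %.2f x %+.1f, R^2 = %.3f\n",
              x$slope, x$intercept, x$r_squared))
  if (x$threshold_defined)
    cat(sprintf("  motion threshold (x-intercept): %.2f; min sounded: %.2f\n",
                x$x_intercept, x$min_sounded))
  else cat("  slope not positive: motion threshold undefined\n")
  invisible(x)
}

#' Cavitation-consistency diagnostic
#'
#' Compares the observed sound pulses against the signature of cavitation
#' bubble collapse: pressure transients of ~50-100 kPa lasting about a
#' microsecond. Reports, per axis, the fold discrepancy between observation
#' and the cavitation reference and flags inconsistency when the discrepancy
#' reaches `criterion` (three orders of magnitude by default). Millipascal
#' pulses lasting milliseconds fail on both axes, excluding cavitation as
#' the sound source.
#'
#' @param events data.frame from [join_events()] (at least one sounded).
#' @param pulse_dur_ms observed sound-pulse duration, ms.
#' @param ref_pressure_pa cavitation reference pressure band, Pa.
#' @param ref_dur_s cavitation reference transient duration, s.
#' @param criterion fold discrepancy that counts as inconsistent.
#' @return A list of class `cavitation_report`: observed values, per-axis
#'   ratios and flags, and an overall `consistent_with_cavitation`.
#' @export
cavitation_check <- function(events, pulse_dur_ms,
                             ref_pressure_pa = c(5e4, 1e5),
                             ref_dur_s = 1e-6, criterion = 1e3) {
  snd <- events[events$sounded, ]
  if (nrow(snd) < 1) stop("no sounded events")
  ptp_max <- max(snd$ptp_pa)
  p_ratio <- min(ref_pressure_pa) / ptp_max
  t_ratio <- (pulse_dur_ms * 1e-3) / ref_dur_s
  p_flag <- p_ratio >= criterion
  t_flag <- t_ratio >= criterion
  structure(list(ptp_max_pa = ptp_max, pulse_dur_ms = pulse_dur_ms,
                 ref_pressure_pa = ref_pressure_pa, ref_dur_s = ref_dur_s,
                 pressure_ratio = p_ratio, duration_ratio = t_ratio,
                 pressure_inconsistent = p_flag,
                 duration_inconsistent = t_flag,
                 consistent_with_cavitation = !(p_flag || t_flag)),
            class = "cavitation_report")
}

#' @export
print.cavitation_report <- function(x, ...) {
  cat("Cavitation-consistency diagnostic\n")
  cat(sprintf("  max ptp: %.3g Pa vs reference %.3g-%.3g Pa -> %.3g-fold %s\n",
              x$ptp_max_pa, x$ref_pressure_pa[1], x$ref_pressure_pa[2],
              x$pressure_ratio,
              if (x$pressure_inconsistent) "too low: inconsistent"
              else "difference: consistent"))
  cat(sprintf("  pulse duration: %.3g ms vs %.3g s -> %.3g-fold %s\n",
              x$pulse_dur_ms, x$ref_dur_s, x$duration_ratio,
              if (x$duration_inconsistent) "too slow: inconsistent"
              else "difference: consistent"))
  cat(sprintf("  verdict: %s with cavitation\n",
              if (x$consistent_with_cavitation) "consistent"
              else "inconsistent"))
  invisible(x)
}
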