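#' Zero-phase band-pass filter a pressure trace
#'
#' 3rd-order Butterworth band-pass (default 1-4 kHz) applied forward and
#' backward (filtfilt), so the filter adds no phase shift and onsets are not
#' delayed.
#'
#' @param trace a `pressure_trace`.
#' @param low_hz,high_hz band edges, Hz.
#' @param order filter order (applied twice by filtfilt).
#' @return The filtered `pressure_trace` (attributes preserved).
#' @export
bandpass <- function(trace, low_hz = 1000, high_hz = 4000, order = 3) {
  stopifnot(inherits(trace, "pressure_trace"), low_hz > 0, high_hz > low_hz)
  nyq <- trace$sample_rate / 2
  if (high_hz >= nyq)
    stop("band edge at or above Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- trace
  out$samples <- signal::filtfilt(bf, trace$samples)
  out
}

#' Noise floor of a recording
#'
#' Defined as `mult` (default 3) times the standard deviation of a
#' background segment (default 67 ms) recorded before the first stimulus.
#'
#' @param trace a `pressure_trace`.
#' @param background_span_s background duration, s, taken from
#'   `background_start_s`.
#' @param background_start_s where the background segment starts, s.
#' @param mult multiplier on the background SD.
#' @return The noise floor, Pa.
#' @export
noise_floor <- function(trace, background_span_s = 0.067,
                        background_start_s = 0, mult = 3) {
  stopifnot(inherits(trace, "pressure_trace"), background_span_s > 0)
  fs <- trace$sample_rate
  i0 <- floor(background_start_s * fs) + 1L
  i1 <- i0 + round(background_span_s * fs) - 1L
  if (i1 > length(trace$samples))
    stop("background segment extends beyond the recording")
  mult * stats::sd(trace$samples[i0:i1])
}

#' Detect per-stimulus sound onsets and amplitudes
#'
#' Within each half-open stimulus window the onset is the first sample whose
#' absolute (band-passed) pressure exceeds `threshold_pa`; windows that never
#' cross the threshold yield no event. The peak-to-peak amplitude is
#' `max - min` within the window. The fixed 0.01 Pa default reflects that
#' reverberant energy in a recording chamber may not dissipate between
#' stimuli, making a pure noise-floor criterion unreliable; if a noise floor
#' is supplied and exceeds the threshold, a warning is raised.
#'
#' @param trace a band-passed `pressure_trace`.
#' @param train a [stimulus_train()].
#' @param threshold_pa onset threshold on `|pressure|`, Pa.
#' @param floor_pa optional measured noise floor, Pa, for the sanity warning.
#' @return A data.frame of `SoundEvent` rows: `stim_idx`, `onset_t` (s),
#'   `ptp_pa`, `above_floor` (TRUE where `ptp` exceeds `floor_pa`;
#'   NA if no floor given). Only stimuli with a detected onset appear.
#' @export
detect_onsets <- function(trace, train, threshold_pa = 0.01,
                          floor_pa = NULL) {
  stopifnot(inherits(trace, "pressure_trace"),
            inherits(train, "stimulus_train"))
  if (!is.null(floor_pa) && threshold_pa < floor_pa)
    warning("onset threshold ", threshold_pa,
            " Pa is below the measured noise floor (", signif(floor_pa, 3),
            " Pa)")
  fs <- trace$sample_rate
  x <- trace$samples
  bounds <- c(train$onsets, (length(x) - 1) / fs + 1 / fs)
  ev <- lapply(seq_len(train$count), function(i) {
    i0 <- floor(bounds[i] * fs) + 1L
    i1 <- min(length(x), ceiling(bounds[i + 1] * fs))
    if (i0 > i1) return(NULL)
    seg <- x[i0:i1]
    hit <- which(abs(seg) > threshold_pa)
    if (!length(hit)) return(NULL)
    data.frame(stim_idx = i, onset_t = (i0 + hit[1] - 2) / fs,
               ptp_pa = max(seg) - min(seg),
               above_floor = if (is.null(floor_pa)) NA
                             else (max(seg) - min(seg)) > floor_pa)
  })
  out <- do.call(rbind, ev)
  if (is.null(out))
    out <- data.frame(stim_idx = integer(0), onset_t = numeric(0),
                      ptp_pa = numeric(0), above_floor = logical(0))
  out
}

#' Time-of-flight correct sound-event onsets
#'
#' Subtracts the propagation delay `distance / c` from detected onset times,
#' so onsets refer to emission at the source. Default medium is air
#' (c = 343 m/s, microphone above the preparation); pass the speed of sound
#' in water/saline for submerged sensors.
#'
#' @param events data.frame from [detect_onsets()].
#' @param distance_m source-to-sensor distance, m.
#' @param c_m_s speed of sound, m/s.
#' @return The events with `onset_t` shifted earlier by `distance_m / c_m_s`.
#' @export
tof_correct <- function(events, distance_m, c_m_s = 343) {
  stopifnot(distance_m >= 0, c_m_s > 0)
  events$onset_t <- events$onset_t - distance_m / c_m_s
  events
}
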