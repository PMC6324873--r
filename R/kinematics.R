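#' Split a kinematic series into per-stimulus windows
#'
#' Half-open windows `[onset_i, onset_(i+1))`; the last window runs to the
#' end of the series.
#'
#' @param series kinematic series (from [differentiate_series()]).
#' @param train a [stimulus_train()].
#' @return A list of data.frames, one per stimulus, each carrying its
#'   `stim_idx` and stimulus onset `t_stim` as attributes.
#' @export
segment_by_stimulus <- function(series, train) {
  stopifnot(inherits(train, "stimulus_train"))
  if (train$count < 1) stop("empty stimulus train")
  if (max(series$t_s) < max(train$onsets))
    stop("series does not cover the stimulus train")
  bounds <- c(train$onsets, Inf)
  lapply(seq_len(train$count), function(i) {
    win <- series[series$t_s >= bounds[i] & series$t_s < bounds[i + 1], ]
    attr(win, "stim_idx") <- i
    attr(win, "t_stim") <- train$onsets[i]
    win
  })
}

#' Kinematic event metrics for one stimulus window
#'
#' Extracts, over the opening phase (gap width increasing), the peak opening
#' velocity, peak positive acceleration and peak deceleration (most negative
#' acceleration), their times, the gap width at the instant of peak
#' deceleration, the maximum gap width, and the gap fraction
#' `100 * gap_at_decel / gap_max`. Acceleration is signed positive when the
#' gap accelerates open. Acceleration extrema are searched only where the
#' opening velocity exceeds `active_frac` of its peak: for a smooth opening
#' both extrema fall inside that region, while outside it double
#' differentiation of tracking jitter produces spurious extrema. A window
#' with no resolvable motion yields a zero event flagged `flat = TRUE`.
#'
#' @param window one element of [segment_by_stimulus()].
#' @param min_gap_um motion below this amplitude counts as flat.
#' @param active_frac velocity fraction delimiting the active opening.
#' @return A one-row data.frame (a `KinematicEvent`).
#' @export
kinematic_peaks <- function(window, min_gap_um = 0.5, active_frac = 0.2) {
  stopifnot(nrow(window) > 0)
  i_max <- which.max(window$w_um)
  gap_max <- window$w_um[i_max] - min(window$w_um[seq_len(i_max)])
  flat <- gap_max < min_gap_um
  if (flat) {
    return(data.frame(stim_idx = attr(window, "stim_idx") %||% NA,
                      t_vpeak = NA, v_peak_mm_s = 0,
                      t_apeak = NA, a_peak_g = 0,
                      t_decel = NA, a_decel_g = 0,
                      gap_at_decel_um = 0, gap_max_um = 0,
                      gap_fraction = NA, flat = TRUE))
  }
  opening <- window[seq_len(i_max), ]
  iv <- which.max(opening$v_mm_s)
  active <- which(opening$v_mm_s >= active_frac * opening$v_mm_s[iv])
  acc_range <- active[active <= iv]
  ia <- acc_range[which.max(opening$a_g[acc_range])]
  # peak deceleration of the opening: most negative acceleration after the
  # velocity peak, while still actively opening
  dec_range <- active[active >= iv]
  id <- dec_range[which.min(opening$a_g[dec_range])]
  w0 <- min(window$w_um[seq_len(i_max)])
  gap_at_decel <- opening$w_um[id] - w0
  data.frame(stim_idx = attr(window, "stim_idx") %||% NA,
             t_vpeak = opening$t_s[iv], v_peak_mm_s = opening$v_mm_s[iv],
             t_apeak = opening$t_s[ia], a_peak_g = opening$a_g[ia],
             t_decel = opening$t_s[id], a_decel_g = opening$a_g[id],
             gap_at_decel_um = gap_at_decel, gap_max_um = gap_max,
             gap_fraction = 100 * gap_at_decel / gap_max, flat = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kinematic events for a whole experiment
#'
#' Convenience wrapper: segments the series by stimulus and extracts the
#' per-window peak metrics.
#'
#' @inheritParams segment_by_stimulus
#' @inheritParams kinematic_peaks
#' @return A data.frame of `KinematicEvent` rows keyed by `stim_idx`.
#' @export
kinematic_events <- function(series, train, min_gap_um = 0.5) {
  do.call(rbind, lapply(segment_by_stimulus(series, train),
                        kinematic_peaks, min_gap_um = min_gap_um))
}
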