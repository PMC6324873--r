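#' @keywords internal
logistic <- function(x) 1 / (1 + exp(-x))

# offset (in units of k*t) of the logistic acceleration extrema from the
# midpoint: the second derivative of L*logistic(k t) peaks at
# sigma = (3 -+ sqrt(3))/6, i.e. at k*t = -+ log((3+sqrt(3))/(3-sqrt(3)))/2...
# computed exactly below.
.logistic_accel_offset <- abs(log((3 - sqrt(3)) / (3 + sqrt(3))))

#' Closed-form peak kinematics of the logistic gap profile
#'
#' For a gap opening `w(t) = gap_max * logistic(k * (t - t0))` the peak
#' opening velocity is `gap_max * k / 4` and the peak opening acceleration
#' `gap_max * k^2 / (6 * sqrt(3))`; peak deceleration mirrors peak
#' acceleration and follows it by `2 * log((3 + sqrt(3)) / (3 - sqrt(3))) / k`
#' seconds. Units follow the inputs (micrometres and 1/s here).
#'
#' @param gap_max_um logistic amplitude, micrometres.
#' @param steepness logistic rate constant k, 1/s.
#' @return A list with `v_peak_mm_s`, `a_peak_m_s2`, `a_peak_g`,
#'   `accel_to_decel_s`.
#' @export
logistic_peak_kinematics <- function(gap_max_um, steepness) {
  v_um_s <- gap_max_um * steepness / 4
  a_um_s2 <- gap_max_um * steepness^2 / (6 * sqrt(3))
  list(v_peak_mm_s = v_um_s * 1e-3,
       a_peak_m_s2 = a_um_s2 * 1e-6,
       a_peak_g = a_um_s2 * 1e-6 / 9.82,
       accel_to_decel_s = 2 * .logistic_accel_offset / steepness)
}

#' Generate a synthetic arytenoid-disc trajectory pair
#'
#' Simulates the mirror-symmetric motion of the two disc markers about the
#' laryngeal midline during a stimulus train. Per stimulus the gap opens
#' along a logistic of amplitude `scale_i * gap_max_um` (facilitation ramp)
#' and steepness `params$steepness`, then relaxes back to rest along a slower
#' logistic. Each bead carries half the gap. Ground-truth peak velocity,
#' acceleration and their times come from the closed-form logistic
#' derivatives.
#'
#' @param params a [disc_motion_params()] object.
#' @param train a [stimulus_train()] object (or numeric onset times, s).
#' @param frame_rate video frame rate, fps. Must satisfy
#'   `frame_rate >= 20 * steepness / (2 * pi)` so the motion is resolvable.
#' @param duration_s total duration, s; default covers the train plus one
#'   inter-stimulus interval.
#' @param seed RNG seed for positional jitter and the facilitation jitter;
#'   `NULL` leaves the RNG state alone.
#' @return A list of class `disc_experiment` with `left` and `right`
#'   trajectory data.frames (`frame`, `t_s`, `x_um`, `y_um`), and `truth`
#'   (class `disc_truth`): generator params, frame rate, the noise-free gap
#'   series `w_um`, and a per-stimulus table with analytic `t_vpeak`,
#'   `v_peak_mm_s`, `t_apeak`, `a_peak_g`, `t_decel` and `gap_max_um`.
#' @export
gen_disc_trajectory <- function(params, train, frame_rate,
                                duration_s = NULL, seed = NULL) {
  stopifnot(inherits(params, "disc_motion_params"))
  onsets <- if (inherits(train, "stimulus_train")) train$onsets else
    sort(as.numeric(train))
  if (length(onsets) < 1) stop("at least one stimulus is required")
  k <- params$steepness
  kc <- params$close_steepness
  if (frame_rate < 20 * k / (2 * pi))
    stop("frame_rate too low to resolve the gap profile: need >= ",
         round(20 * k / (2 * pi)), " fps")
  event_dur <- params$t_open_s + params$hold_s + 6 / kc
  if (length(onsets) > 1 && min(diff(onsets)) < event_dur)
    stop("inter-stimulus interval shorter than the open+close duration")
  if (is.null(duration_s))
    duration_s <- max(onsets) + max(event_dur * 1.5,
                                    if (length(onsets) > 1)
                                      stats::median(diff(onsets)) else 0)
  if (!is.null(seed)) set.seed(seed)

  n <- floor(duration_s * frame_rate) + 1L
  t <- (seq_len(n) - 1L) / frame_rate
  idx <- seq_along(onsets)
  scale <- 1 - exp(-idx / params$facil_tau)
  if (params$scale_jitter_sd > 0)
    scale <- scale * exp(stats::rnorm(length(idx), 0,
                                      params$scale_jitter_sd))
  w <- numeric(n)
  for (i in idx) {
    t0 <- onsets[i] + params$t_open_s
    w <- w + scale[i] * params$gap_max_um *
      (logistic(k * (t - t0)) - logistic(kc * (t - t0 - params$hold_s)))
  }

  pk <- logistic_peak_kinematics(params$gap_max_um, k)
  stim <- data.frame(
    stim_idx = idx,
    t_stim = onsets,
    scale = scale,
    t_vpeak = onsets + params$t_open_s,
    t_apeak = onsets + params$t_open_s - .logistic_accel_offset / k,
    t_decel = onsets + params$t_open_s + .logistic_accel_offset / k,
    v_peak_mm_s = scale * pk$v_peak_mm_s,
    a_peak_m_s2 = scale * pk$a_peak_m_s2,
    a_peak_g = scale * pk$a_peak_g,
    gap_max_um = scale * params$gap_max_um)

  half_sep <- params$rest_separation_um / 2
  jit <- function() if (params$rest_jitter_um > 0)
    stats::rnorm(n, 0, params$rest_jitter_um) else numeric(n)
  left <- data.frame(frame = seq_len(n), t_s = t,
                     x_um = -half_sep - w / 2 + jit(), y_um = jit())
  right <- data.frame(frame = seq_len(n), t_s = t,
                      x_um = half_sep + w / 2 + jit(), y_um = jit())
  truth <- structure(list(params = params, frame_rate = frame_rate,
                          t_s = t, w_um = w, stim = stim,
                          train = if (inherits(train, "stimulus_train"))
                            train else stimulus_train(
                              rate_hz = if (length(onsets) > 1)
                                1 / stats::median(diff(onsets)) else 1,
                              count = length(onsets), t_first = onsets[1])),
                     class = "disc_truth")
  structure(list(left = left, right = right, truth = truth),
            class = "disc_experiment")
}

#' Render bead trajectories into a synthetic image stack
#'
#' Draws each carbon microsphere as an inverted 2D Gaussian spot
#' (sigma = diameter / 4) on a bright background at its subpixel centre,
#' with optional additive Gaussian pixel noise. The pixel signal-to-noise
#' ratio is `depth / noise_sd`.
#'
#' @param exp_or_pair a `disc_experiment` or a list with `left`/`right`
#'   trajectory data.frames.
#' @param bead_diam_um bead diameter, micrometres; must map to at least 3 px.
#' @param px_size_um pixel calibration, micrometres per pixel.
#' @param noise_sd SD of additive pixel noise (intensity units; background is
#'   `bg`, spot depth `depth`).
#' @param seed RNG seed for the pixel noise.
#' @param frame_dim_px optional `c(ny, nx)`; default fits the trajectories
#'   with a margin.
#' @param bg,depth background intensity and spot depth.
#' @return A `frame_stack`: list with `frames` (ny x nx x nframes array),
#'   `frame_rate`, `px_size_um` and `origin_um` (`c(x0, y0)`, the world
#'   coordinate of pixel (1, 1)).
#' @export
render_bead_frames <- function(exp_or_pair, bead_diam_um = 80,
                               px_size_um = 5, noise_sd = 0, seed = NULL,
                               frame_dim_px = NULL, bg = 0.75, depth = 0.6) {
  pair <- if (inherits(exp_or_pair, "disc_experiment"))
    exp_or_pair[c("left", "right")] else exp_or_pair
  frame_rate <- if (inherits(exp_or_pair, "disc_experiment"))
    exp_or_pair$truth$frame_rate else attr(exp_or_pair, "frame_rate")
  sigma_px <- bead_diam_um / 4 / px_size_um
  if (bead_diam_um / px_size_um < 3)
    stop("bead must span at least 3 pixels")
  xs <- c(pair$left$x_um, pair$right$x_um)
  ys <- c(pair$left$y_um, pair$right$y_um)
  margin_um <- (4 * sigma_px + 8) * px_size_um
  if (is.null(frame_dim_px)) {
    nx <- ceiling((diff(range(xs)) + 2 * margin_um) / px_size_um)
    ny <- ceiling((diff(range(ys)) + 2 * margin_um) / px_size_um)
    origin <- c(min(xs) - margin_um, min(ys) - margin_um)
  } else {
    ny <- frame_dim_px[1]; nx <- frame_dim_px[2]
    origin <- c(mean(range(xs)) - nx / 2 * px_size_um,
                mean(range(ys)) - ny / 2 * px_size_um)
  }
  n <- nrow(pair$left)
  to_px <- function(v, o) (v - o) / px_size_um + 1
  lx <- to_px(pair$left$x_um, origin[1]);  ly <- to_px(pair$left$y_um, origin[2])
  rx <- to_px(pair$right$x_um, origin[1]); ry <- to_px(pair$right$y_um, origin[2])
  lim <- 2 * sigma_px
  if (any(c(lx, rx) < 1 + lim) || any(c(lx, rx) > nx - lim) ||
      any(c(ly, ry) < 1 + lim) || any(c(ly, ry) > ny - lim))
    stop("bead leaves the frame; enlarge frame_dim_px")
  if (!is.null(seed)) set.seed(seed)
  colv <- matrix(rep(seq_len(nx), each = ny), ny, nx)  # x coordinate
  rowv <- matrix(rep(seq_len(ny), nx), ny, nx)         # y coordinate
  frames <- array(0, dim = c(ny, nx, n))
  for (i in seq_len(n)) {
    f <- bg -
      depth * exp(-((colv - lx[i])^2 + (rowv - ly[i])^2) / (2 * sigma_px^2)) -
      depth * exp(-((colv - rx[i])^2 + (rowv - ry[i])^2) / (2 * sigma_px^2))
    if (noise_sd > 0) f <- f + stats::rnorm(ny * nx, 0, noise_sd)
    frames[, , i] <- f
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 px_size_um = px_size_um, origin_um = origin),
            class = "frame_stack")
}

#' Sound-pressure trace container
#'
#' @param samples pressure samples, Pa.
#' @param sample_rate sample rate, Hz.
#' @param channel sensor type: microphone, hydrophone or laser.
#' @param source_distance_m source-to-sensor distance, m (for time-of-flight
#'   correction).
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(samples, sample_rate,
                           channel = c("microphone", "hydrophone", "laser"),
                           source_distance_m = 0) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sample_rate > 0,
            source_distance_m >= 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 channel = match.arg(channel),
                 source_distance_m = source_distance_m),
            class = "pressure_trace")
}

# one damped two-tone pulse with a broadband attack, scaled so that its
# realized peak-to-peak amplitude equals ptp_pa; when calibrate_band is
# given, the amplitude is calibrated on the band-passed waveform, since
# received levels are measured on the filtered trace
.render_pulse <- function(fs, df1, df2, amp2, decay, attack_ms, attack_gain,
                          ptp_pa, dur_s = NULL, calibrate_band = NULL) {
  if (is.null(dur_s)) dur_s <- 6 / decay
  np <- max(32L, round(dur_s * fs))
  tau <- (seq_len(np) - 1L) / fs
  u <- (sin(2 * pi * df1 * tau) +
          if (amp2 > 0) amp2 * sin(2 * pi * df2 * tau) else 0) *
    exp(-decay * tau)
  na <- round(attack_ms * 1e-3 * fs)
  if (na > 2 && attack_gain > 0) {
    burst <- stats::rnorm(na)
    hi <- min(8000, 0.45 * fs)
    bf <- signal::butter(2, c(500, hi) / (fs / 2), type = "pass")
    burst <- signal::filtfilt(bf, c(burst, numeric(na)))[seq_len(na)]
    burst <- burst / max(abs(burst)) * attack_gain * max(abs(u))
    burst <- burst * seq(1, 0, length.out = na)  # decaying attack
    u[seq_len(na)] <- u[seq_len(na)] + burst
  }
  nt <- min(np, round(1e-3 * fs))  # 1 ms end taper
  u[(np - nt + 1):np] <- u[(np - nt + 1):np] *
    (0.5 + 0.5 * cos(pi * seq_len(nt) / nt))
  ref <- if (is.null(calibrate_band)) u else {
    bf <- signal::butter(3, calibrate_band / (fs / 2), type = "pass")
    signal::filtfilt(bf, c(numeric(np), u, numeric(np)))[np + seq_len(np)]
  }
  u * ptp_pa / (max(ref) - min(ref))
}

#' Synthesize the per-stimulus sound-pressure trace of an ex vivo experiment
#'
#' For every stimulus whose ground-truth peak disc velocity exceeds the
#' velocity threshold, emits a damped two-tone pulse starting
#' `lag_onset_s` after the instant of peak velocity, with peak-to-peak
#' amplitude `min(amp_intercept + amp_slope * v_peak, saturation)` (mPa scale
#' against mm/s). Subthreshold stimuli emit nothing. Gaussian background
#' noise is added throughout.
#'
#' @param truth a `disc_truth` object from [gen_disc_trajectory()].
#' @param p a [pulse_sound_params()] object.
#' @param sample_rate audio sample rate, Hz; must be at least `4 * df2_hz`.
#' @param seed RNG seed.
#' @param duration_s trace duration, s; default covers the experiment.
#' @param source_distance_m if positive, pulses are delayed by the
#'   time of flight `distance / 343` and the distance is recorded on the
#'   trace.
#' @return A `pressure_trace` with attribute `sound_truth`: data.frame
#'   (`stim_idx`, `sounded`, `t_onset` — emission time, s — and `ptp_mpa`).
#' @export
synth_pulse_sound <- function(truth, p, sample_rate = 30000, seed = NULL,
                              duration_s = NULL, source_distance_m = 0) {
  stopifnot(inherits(truth, "disc_truth"),
            inherits(p, "pulse_sound_params"))
  if (sample_rate < 4 * p$df2_hz)
    stop("sample_rate must be at least 4x df2_hz")
  if (!is.null(seed)) set.seed(seed)
  fs <- sample_rate
  if (is.null(duration_s)) duration_s <- max(truth$t_s) + 0.02
  n <- floor(duration_s * fs) + 1L
  x <- if (p$noise_sd_pa > 0) stats::rnorm(n, 0, p$noise_sd_pa) else numeric(n)
  st <- truth$stim
  tof <- source_distance_m / 343
  sounded <- st$v_peak_mm_s > p$v_threshold_mm_s
  ptp_mpa <- pmin(p$amp_intercept_mpa + p$amp_slope * st$v_peak_mm_s,
                  p$ptp_saturation_mpa)
  onset <- st$t_vpeak + p$lag_onset_s
  sounded <- sounded & ptp_mpa > 0
  for (i in which(sounded)) {
    i0 <- round((onset[i] + tof) * fs) + 1L
    pulse <- .render_pulse(fs, p$df1_hz, p$df2_hz, p$amp2, p$decay,
                           p$attack_ms, p$attack_gain, ptp_mpa[i] * 1e-3,
                           calibrate_band = c(1000, 4000))
    j <- i0:min(n, i0 + length(pulse) - 1L)
    x[j] <- x[j] + pulse[seq_along(j)]
  }
  tr <- pressure_trace(x, fs, "microphone", source_distance_m)
  attr(tr, "sound_truth") <- data.frame(
    stim_idx = st$stim_idx, sounded = sounded,
    t_onset = ifelse(sounded, (round((onset + tof) * fs)) / fs - tof, NA),
    ptp_mpa = ifelse(sounded, ptp_mpa, NA))
  tr
}

#' Synthesize an advertisement call
#'
#' Builds a biphasic pulse train (fast trill then slow trill, separated by a
#' 0.25 s pause). Every pulse is a broadband attack followed by a sustained
#' two-tone dyad. With `amp2 = 0` the call carries a single frequency band
#' (the outcome observed after disrupting the elastic-cartilage septa).
#'
#' @param spec a [call_spec()] object.
#' @param seed RNG seed.
#' @return A `pressure_trace` (44.1 kHz by default) with attribute
#'   `call_truth`: data.frame (`pulse_idx`, `trill`, `t_onset`).
#' @export
synth_advertisement_call <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "call_spec"))
  if (!is.null(seed)) set.seed(seed)
  fs <- spec$sample_rate
  onsets <- numeric(0); trill <- character(0)
  if (spec$n_fast > 0) {
    onsets <- c(onsets, 0.05 + (seq_len(spec$n_fast) - 1) / spec$pulse_rate_fast)
    trill <- c(trill, rep("fast", spec$n_fast))
  }
  if (spec$n_slow > 0) {
    t0 <- if (length(onsets)) max(onsets) + spec$pulse_dur_ms * 1e-3 + 0.25
          else 0.05
    onsets <- c(onsets, t0 + (seq_len(spec$n_slow) - 1) / spec$pulse_rate_slow)
    trill <- c(trill, rep("slow", spec$n_slow))
  }
  dur <- max(onsets) + spec$pulse_dur_ms * 1e-3 + 0.05
  n <- floor(dur * fs) + 1L
  x <- if (spec$noise_sd_pa > 0) stats::rnorm(n, 0, spec$noise_sd_pa)
       else numeric(n)
  for (i in seq_along(onsets)) {
    pulse <- .render_pulse(fs, spec$df1_hz, spec$df2_hz, spec$amp2,
                           spec$decay, spec$attack_ms, spec$attack_gain,
                           ptp_pa = 2 * spec$amp_pa,
                           dur_s = spec$pulse_dur_ms * 1e-3)
    i0 <- round(onsets[i] * fs) + 1L
    j <- i0:min(n, i0 + length(pulse) - 1L)
    x[j] <- x[j] + pulse[seq_along(j)]
  }
  tr <- pressure_trace(x, fs, "hydrophone")
  attr(tr, "call_truth") <- data.frame(pulse_idx = seq_along(onsets),
                                       trill = trill, t_onset = onsets)
  tr
}
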