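# shared fixtures and independent oracles, built in code at test time

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# gentle disc motion resolvable at 10 kfps (frame_rate >= 20 * k / 2pi),
# used for rendered-stack tracking validation
gentle_params <- function(...) {
  args <- list(gap_max_um = 100, steepness = 2000, rest_jitter_um = 0,
               scale_jitter_sd = 0, facil_tau = 0.01)
  over <- list(...)
  args[names(over)] <- over
  do.call(disc_motion_params, args)
}

# rendered three-stimulus experiment at 10 kfps, pixel SNR 10
rendered_experiment <- function(noise_sd = 0.06, seed = 2) {
  train <- stimulus_train(40, 3, t_first = 0.02)
  ex <- gen_disc_trajectory(gentle_params(), train, frame_rate = 10000,
                            seed = 1)
  stack <- render_bead_frames(ex, bead_diam_um = 80, px_size_um = 5,
                              noise_sd = noise_sd, seed = seed)
  list(ex = ex, stack = stack, train = train)
}

um_to_px <- function(um, origin, px_size) (um - origin) / px_size + 1

rest_center_px <- function(traj, stack) {
  round(c(um_to_px(traj$x_um[1], stack$origin_um[1], stack$px_size_um),
          um_to_px(traj$y_um[1], stack$origin_um[2], stack$px_size_um)))
}

# full mechanism experiment at the generator defaults: 40 kfps kinematics,
# 30 kHz audio, analysed with the 13-frame smoothing window
mech_experiment <- function(seed = 1, n_stim = 40, jitter = TRUE) {
  p <- if (jitter) disc_motion_params()
       else disc_motion_params(rest_jitter_um = 0, scale_jitter_sd = 0)
  sp <- pulse_sound_params(noise_sd_pa = if (jitter) 0.002 else 0)
  train <- stimulus_train(40, n_stim, t_first = 0.1)
  ex <- gen_disc_trajectory(p, train, frame_rate = 40000, seed = seed)
  snd <- synth_pulse_sound(ex$truth, sp,
                           sample_rate = 30000, seed = seed + 1000,
                           duration_s = max(ex$truth$t_s) + 0.02)
  ks <- differentiate_series(
    compute_gap_width(ex$left, ex$right, rest_frames = 1:2000),
    smooth_window = 13)
  kev <- kinematic_events(ks, train)
  sev <- detect_onsets(bandpass(snd), train, threshold_pa = 0.01)
  list(ex = ex, snd = snd, train = train, kev = kev, sev = sev,
       coupled = join_events(kev, sev))
}

# oracle for subpixel shift recovery: argmax of the normalized
# cross-correlation evaluated on a 20x-refined shift grid via bilinear
# interpolation of the image -- independent of the quadratic-refinement path
oracle_shift <- function(tpl_patch, frame, center_px, grid = seq(-1, 1, 0.05)) {
  h <- (nrow(tpl_patch) - 1) / 2
  t0 <- tpl_patch - mean(tpl_patch)
  bilin <- function(img, y, x) {
    y0 <- floor(y); x0 <- floor(x); fy <- y - y0; fx <- x - x0
    img[y0, x0] * (1 - fy) * (1 - fx) + img[y0 + 1, x0] * fy * (1 - fx) +
      img[y0, x0 + 1] * (1 - fy) * fx + img[y0 + 1, x0 + 1] * fy * fx
  }
  rows <- (center_px[2] - h):(center_px[2] + h)
  cols <- (center_px[1] - h):(center_px[1] + h)
  best <- -Inf; best_s <- NA
  for (s in grid) {
    patch <- outer(rows, cols,
                   Vectorize(function(r, c) bilin(frame, r, c + s)))
    p0 <- patch - mean(patch)
    v <- sum(t0 * p0) / sqrt(sum(t0^2) * sum(p0^2))
    if (v > best) { best <- v; best_s <- s }
  }
  best_s
}

# printed species table rows used as dyad generator inputs
table1_df_pairs <- function() {
  t1 <- xenopus_table1()
  t1[!is.na(t1$df1_hz), c("species", "df1_hz", "df2_hz", "ratio", "interval")]
}

# one long two-tone pulse from printed species means, through the full
# dyads stage
measure_species_pulse <- function(df1, df2, seed) {
  cs <- call_spec(df1, df2, n_fast = 1, n_slow = 0, pulse_rate_fast = 1,
                  pulse_dur_ms = 500, decay = 4)
  trc <- synth_advertisement_call(cs, seed = seed)
  segs <- segment_pulses(trc, attack_ms = 2)
  measure_dyad(segs[[1]])
}
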