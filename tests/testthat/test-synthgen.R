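test_that("zero gap amplitude yields flat tracks and zero peak velocity", {
  p <- disc_motion_params(gap_max_um = 0, steepness = 2000,
                          rest_jitter_um = 0, scale_jitter_sd = 0)
  ex <- gen_disc_trajectory(p, stimulus_train(40, 2, 0.02),
                            frame_rate = 10000)
  expect_equal(diff(range(ex$left$x_um)), 0)
  expect_equal(diff(range(ex$right$x_um)), 0)
  expect_equal(ex$truth$stim$v_peak_mm_s, c(0, 0))
})

test_that("analytic logistic peak velocity matches the sampled maximum", {
  p <- gentle_params()  # k = 2000/s, gap 100 um
  ex <- gen_disc_trajectory(p, stimulus_train(40, 1, 0.02),
                            frame_rate = 10000)
  w <- ex$truth$w_um
  dt <- 1 / 10000
  v_num <- max(diff(w, lag = 2) / (2 * dt)) * 1e-3  # central diff, mm/s
  v_ana <- logistic_peak_kinematics(100, 2000)$v_peak_mm_s
  expect_equal(v_ana, 2000 * 100 / 4 * 1e-3)
  expect_lt(abs(v_num / v_ana - 1), 0.01)
  expect_equal(ex$truth$stim$v_peak_mm_s, v_ana * ex$truth$stim$scale)
})

test_that("default parameters reproduce the reported kinematic regime", {
  pk <- logistic_peak_kinematics(disc_motion_params()$gap_max_um,
                                 disc_motion_params()$steepness)
  expect_equal(pk$v_peak_mm_s, 50.3, tolerance = 0.01)
  expect_equal(pk$a_peak_g, 13.5, tolerance = 0.01)
})

test_that("trajectory generation is deterministic under a fixed seed", {
  p <- gentle_params(rest_jitter_um = 0.05, scale_jitter_sd = 0.1)
  tr <- stimulus_train(40, 3, 0.02)
  a <- gen_disc_trajectory(p, tr, 10000, seed = 7)
  b <- gen_disc_trajectory(p, tr, 10000, seed = 7)
  expect_identical(a, b)
})

test_that("too-short inter-stimulus intervals are rejected", {
  expect_error(gen_disc_trajectory(gentle_params(), c(0.02, 0.021), 10000),
               "inter-stimulus")
})

test_that("static noiseless rendering gives identical frames", {
  p <- disc_motion_params(gap_max_um = 0, steepness = 2000,
                          rest_jitter_um = 0, scale_jitter_sd = 0)
  ex <- gen_disc_trajectory(p, stimulus_train(40, 1, 0.005),
                            frame_rate = 10000, duration_s = 0.01)
  st <- render_bead_frames(ex, noise_sd = 0)
  expect_equal(st$frames[, , 1], st$frames[, , dim(st$frames)[3]])
})

test_that("a subpixel bead shift moves the rendered darkness centroid", {
  # 0.30 px shift between frames -> centroid moves 0.30 +- 0.02 px
  traj <- list(
    left = data.frame(frame = 1:2, t_s = c(0, 1e-4),
                      x_um = c(-75, -75 - 0.30 * 5), y_um = c(0, 0)),
    right = data.frame(frame = 1:2, t_s = c(0, 1e-4),
                       x_um = c(75, 75), y_um = c(0, 0)))
  attr(traj, "frame_rate") <- 10000
  st <- render_bead_frames(traj, bead_diam_um = 80, px_size_um = 5,
                           noise_sd = 0)
  centroid_x <- function(f) {
    dark <- max(f) - f
    sum(colSums(dark) * seq_len(ncol(f))) / sum(dark)
  }
  # isolate the left bead's columns
  lx <- um_to_px(-75, st$origin_um[1], 5)
  cols <- round(lx + (-14:14))
  shift <- centroid_x(st$frames[, cols, 2]) - centroid_x(st$frames[, cols, 1])
  expect_equal(shift, -0.30, tolerance = 0.02)
})

test_that("bead size maps to the documented spot size", {
  # 80 um bead at 5 um/px: sigma = 80/4 = 20 um = 4 px, spot 'diameter' 16 px
  expect_equal(80 / 4 / 5 * 4, 16)
})

test_that("beads leaving the frame are rejected", {
  ex <- gen_disc_trajectory(gentle_params(), stimulus_train(40, 1, 0.02),
                            10000)
  expect_error(render_bead_frames(ex, frame_dim_px = c(20, 20)),
               "leaves the frame")
})

test_that("subthreshold stimuli emit pure noise", {
  p <- gentle_params(gap_max_um = 10)  # v_peak = 5 mm/s, far below 40.5
  ex <- gen_disc_trajectory(p, stimulus_train(40, 3, 0.02), 10000)
  ps <- pulse_sound_params(noise_sd_pa = 0.002)
  tr <- synth_pulse_sound(ex$truth, ps, seed = 3)
  expect_true(all(!attr(tr, "sound_truth")$sounded))
  expect_lt(max(abs(tr$samples)), 5.5 * ps$noise_sd_pa)
})

test_that("energy stays local: quiet outside pulse windows", {
  me <- cached("mech1", mech_experiment(seed = 1))
  truth <- attr(me$snd, "sound_truth")
  fs <- me$snd$sample_rate
  mask <- rep(TRUE, length(me$snd$samples))
  for (t0 in truth$t_onset[truth$sounded]) {
    i0 <- max(1, round(t0 * fs) - 10)
    mask[i0:min(length(mask), i0 + round(0.015 * fs))] <- FALSE
  }
  ns <- pulse_sound_params()$noise_sd_pa
  expect_lt(max(abs(me$snd$samples[mask])), 5.5 * ns)
})

test_that("the facilitation ramp silences the first stimuli", {
  me <- cached("mech_nojit", mech_experiment(seed = 1, jitter = FALSE))
  truth <- attr(me$snd, "sound_truth")
  # stimulus 1 emits nothing; stimulus 2 barely crosses the emission
  # threshold but stays below the 0.01 Pa detection threshold; stimulus 3
  # is the first detectable pulse
  expect_false(truth$sounded[1])
  expect_lt(truth$ptp_mpa[2], 20)
  expect_true(truth$sounded[3] && truth$ptp_mpa[3] > 20)
})

test_that("generated peak-to-peak amplitude follows the published line", {
  # v_peak = 75 mm/s on the line 5.2 x - 210.5 -> 179.5 mPa, under the
  # 180 mPa saturation
  expect_equal(min(5.2 * 75 - 210.5, 180), 179.5)
  p <- gentle_params(gap_max_um = 150)  # v_peak = 150*2000/4 = 75 mm/s
  ex <- gen_disc_trajectory(p, stimulus_train(40, 1, 0.05), 10000,
                            duration_s = 0.12)
  snd <- synth_pulse_sound(ex$truth, pulse_sound_params(noise_sd_pa = 0),
                           seed = 4)
  truth <- attr(snd, "sound_truth")
  expect_equal(truth$ptp_mpa[1], 179.5, tolerance = 1e-9)
  # amplitudes are calibrated on the band-passed waveform, where received
  # levels are measured; within ripple of the target
  filt_ptp <- diff(range(bandpass(snd)$samples)) * 1e3
  expect_lt(abs(filt_ptp / 179.5 - 1), 0.02)
})

test_that("a sampling rate below 4x DF2 is rejected", {
  ex <- gen_disc_trajectory(gentle_params(), stimulus_train(40, 1, 0.02),
                            10000)
  expect_error(synth_pulse_sound(ex$truth, pulse_sound_params(),
                                 sample_rate = 8000), "4x")
})

test_that("a single-pulse call peaks at the requested dyad frequencies", {
  m <- cached("borealis_pulse", measure_species_pulse(1253, 2504, seed = 11))
  expect_equal(m$df1_hz, 1253, tolerance = 1e-3)
  expect_equal(m$df2_hz, 2504, tolerance = 1e-3)
})

test_that("a fast trill at 60 pulses/s for 1 s yields 60 onsets", {
  cs <- call_spec(1253, 2504, n_fast = 60, n_slow = 0)
  trc <- synth_advertisement_call(cs, seed = 5)
  truth <- attr(trc, "call_truth")
  expect_equal(nrow(truth), 60)
  expect_equal(diff(truth$t_onset), rep(1 / 60, 59), tolerance = 1e-9)
  segs <- segment_pulses(trc)
  expect_length(segs, 60)
})

test_that("zeroing the second component produces a single-band call", {
  cs <- call_spec(1500, 3000, amp2 = 0, n_fast = 1, n_slow = 0,
                  pulse_rate_fast = 5, pulse_dur_ms = 100)
  m <- measure_dyad(segment_pulses(synth_advertisement_call(cs, seed = 7))[[1]])
  expect_true(m$single_band)
  expect_true(is.na(m$df2_hz))
  expect_equal(m$df1_hz, 1500, tolerance = 1)
})

test_that("overlapping pulse trains are rejected", {
  expect_error(call_spec(1000, 2000, pulse_rate_fast = 60,
                         pulse_dur_ms = 20), "overlap")
})
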