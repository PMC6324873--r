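test_that("a template correlates with its own frame at exactly 1", {
  re <- cached("rexp", rendered_experiment())
  ctr <- rest_center_px(re$ex$left, re$stack)
  tpl <- extract_template(re$stack, 1, ctr, 10)
  trj <- track_bead(re$stack, tpl, search_radius_px = 1)
  expect_equal(trj$score[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(tpl$center_offset_px)), 0.5)
})

test_that("clipped template windows are rejected", {
  re <- cached("rexp", rendered_experiment())
  expect_error(extract_template(re$stack, 1, c(3, 3), 10), "clipped")
})

test_that("a static noiseless bead tracks with zero error", {
  p <- disc_motion_params(gap_max_um = 0, steepness = 2000,
                          rest_jitter_um = 0, scale_jitter_sd = 0)
  ex <- gen_disc_trajectory(p, stimulus_train(40, 1, 0.005), 10000,
                            duration_s = 0.01)
  st <- render_bead_frames(ex, noise_sd = 0)
  ctr <- rest_center_px(ex$left, st)
  trj <- track_bead(st, extract_template(st, 1, ctr, 10), 2)
  expect_lt(diff(range(trj$x_um)), 1e-4)
  expect_lt(max(abs(trj$x_um - ex$left$x_um)), 1e-4 * st$px_size_um)
})

test_that("a known 0.30 px shift is recovered and agrees with the
          upsampled-correlation oracle", {
  traj <- list(
    left = data.frame(frame = 1:2, t_s = c(0, 1e-4),
                      x_um = c(-75, -75 + 0.30 * 5), y_um = c(0, 0)),
    right = data.frame(frame = 1:2, t_s = c(0, 1e-4),
                       x_um = c(75, 75), y_um = c(0, 0)))
  attr(traj, "frame_rate") <- 10000
  st <- render_bead_frames(traj, noise_sd = 0)
  ctr <- rest_center_px(traj$left, st)
  tpl <- extract_template(st, 1, ctr, 10)
  trj <- track_bead(st, tpl, 2)
  shift_px <- (trj$x_um[2] - trj$x_um[1]) / st$px_size_um
  expect_equal(shift_px, 0.30, tolerance = 0.05)
  oracle <- oracle_shift(tpl$patch, st$frames[, , 2], tpl$center_px)
  expect_equal(shift_px, oracle, tolerance = 0.05)
})

test_that("position RMSE stays below 0.1 px at pixel SNR 10", {
  # sinusoidal subpixel motion, amplitude 0.4 px, SNR = depth/noise = 10
  n <- 120
  xs <- -75 + 0.4 * 5 * sin(2 * pi * (0:(n - 1)) / 40)
  traj <- list(
    left = data.frame(frame = 1:n, t_s = (0:(n - 1)) * 1e-4,
                      x_um = xs, y_um = numeric(n)),
    right = data.frame(frame = 1:n, t_s = (0:(n - 1)) * 1e-4,
                       x_um = rep(75, n), y_um = numeric(n)))
  attr(traj, "frame_rate") <- 10000
  st <- render_bead_frames(traj, noise_sd = 0.06, seed = 9)
  ctr <- rest_center_px(traj$left, st)
  trj <- track_bead(st, extract_template(st, 1:40, ctr, 10), 3)
  rmse <- sqrt(mean((trj$x_um - xs)^2)) / st$px_size_um
  expect_lt(rmse, 0.1)
})

test_that("tracking is equivariant under whole-pixel stack translation", {
  re <- cached("rexp", rendered_experiment())
  st <- re$stack
  shifted <- st
  d <- dim(st$frames)
  shifted$frames <- st$frames[, c((d[2] - 1):d[2], 1:(d[2] - 2)), ]  # +2 px in x
  ctr <- rest_center_px(re$ex$left, st)
  trj0 <- track_bead(st, extract_template(st, 1:150, ctr, 10), 3)
  ctr2 <- ctr + c(2, 0)
  trj2 <- track_bead(shifted, extract_template(shifted, 1:150, ctr2, 10), 3)
  expect_equal(trj2$x_um - trj0$x_um,
               rep(2 * st$px_size_um, nrow(trj0)), tolerance = 1e-6)
})

test_that("rendered-stack tracking recovers peak kinematics at 10 kfps", {
  re <- cached("rexp", rendered_experiment())
  st <- re$stack; ex <- re$ex
  trL <- track_bead(st, extract_template(st, 1:150,
                                         rest_center_px(ex$left, st), 10), 3)
  trR <- track_bead(st, extract_template(st, 1:150,
                                         rest_center_px(ex$right, st), 10), 3)
  rmse <- sqrt(mean(((trL$x_um - ex$left$x_um)^2 +
                       (trL$y_um - ex$left$y_um)^2) / 2)) / st$px_size_um
  expect_lt(rmse, 0.1)
  ks <- differentiate_series(
    compute_gap_width(trL, trR, rest_frames = 1:150), smooth_window = 13)
  cmp <- merge(kinematic_events(ks, re$train), ex$truth$stim,
               by = "stim_idx")
  expect_lt(max(abs(cmp$v_peak_mm_s.x / cmp$v_peak_mm_s.y - 1)), 0.05)
  expect_lt(max(abs(cmp$a_peak_g.x / cmp$a_peak_g.y - 1)), 0.10)
  expect_equal(max(ks$w_um), 100, tolerance = 1)  # gap_max recovered
})

test_that("gap width follows its definition", {
  n <- 10
  mk <- function(x) data.frame(frame = 1:n, t_s = (0:(n - 1)) * 1e-4,
                               x_um = x, y_um = numeric(n))
  static <- compute_gap_width(mk(rep(-50, n)), mk(rep(50, n)),
                              rest_frames = 1:3)
  expect_equal(static$w_um, numeric(n))
  # each bead moving 10 um away from the midline -> w = 20 um
  away <- compute_gap_width(mk(c(rep(-50, 5), rep(-60, 5))),
                            mk(c(rep(50, 5), rep(60, 5))),
                            rest_frames = 1:5)
  expect_equal(away$w_um[6:10], rep(20, 5))
  expect_error(compute_gap_width(mk(rep(-50, n)), mk(rep(50, n))),
               "rest interval")
})

test_that("differentiation recovers analytic derivatives", {
  n <- 201; dt <- 1e-4
  t <- (0:(n - 1)) * dt
  flat <- differentiate_series(data.frame(frame = 1:n, t_s = t,
                                          w_um = rep(5, n)))
  expect_equal(flat$v_mm_s, numeric(n))
  expect_equal(flat$a_g, numeric(n))
  # w = 1/2 a0 t^2 with a0 = 98.2 m/s^2 -> recovered within 1 %, = 10 g
  a0 <- 98.2
  par <- differentiate_series(data.frame(frame = 1:n, t_s = t,
                                         w_um = 0.5 * a0 * t^2 * 1e6))
  mid <- 50:150
  expect_lt(max(abs(par$a_m_s2[mid] / a0 - 1)), 0.01)
  expect_equal(par$a_g[mid], rep(10, length(mid)), tolerance = 0.01)
  expect_error(differentiate_series(data.frame(frame = 1:3, t_s = t[1:3],
                                               w_um = 1:3),
                                    smooth_window = 5), "window")
})
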