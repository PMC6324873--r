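test_that("pulse segmentation finds pulses at their true onsets", {
  cs <- call_spec(1253, 2504, n_fast = 30, n_slow = 0)
  trc <- synth_advertisement_call(cs, seed = 5)
  segs <- segment_pulses(trc)
  truth <- attr(trc, "call_truth")
  expect_length(segs, nrow(truth))
  onset_err_ms <- vapply(seq_along(segs), function(i)
    abs(segs[[i]]$t_onset - truth$t_onset[i]) * 1e3, numeric(1))
  expect_lt(max(onset_err_ms), 1)
  # silent trace: empty with a warning
  silent <- pressure_trace(numeric(44100), 44100)
  expect_warning(empty <- segment_pulses(silent, threshold_pa = 1e-3),
                 "no pulses")
  expect_length(empty, 0)
})

test_that("the power spectrum locates tones and satisfies Parseval", {
  fs <- 44100
  t <- seq(0, 0.2, by = 1 / fs)
  x <- sin(2 * pi * 2000 * t)
  ps <- power_spectrum(x, pad_factor = 4, sample_rate = fs)
  bin <- ps$freq_hz[2] - ps$freq_hz[1]
  expect_lt(abs(ps$freq_hz[which.max(ps$power)] - 2000), bin / 2 + 1e-9)
  # Parseval: one-sided power (doubled away from DC/Nyquist) over nfft
  # equals the windowed time-domain energy
  nfft <- attr(ps, "nfft")
  mult <- c(1, rep(2, nrow(ps) - 2), 1)
  expect_equal(sum(mult * ps$power) / nfft, attr(ps, "windowed_energy"),
               tolerance = 0.01)
  # two-tone pulse shows two peaks
  x2 <- x + sin(2 * pi * 1253 * t) + sin(2 * pi * 2504 * t)
  ps2 <- power_spectrum(x2, sample_rate = fs)
  df2 <- find_dominant_frequencies(ps2, min_sep = 100)
  expect_equal(df2$n_peaks >= 2, TRUE)
  expect_error(power_spectrum(numeric(32), sample_rate = fs), "too short")
})

test_that("dominant-frequency extraction is accurate to 0.5 %", {
  m <- cached("borealis_pulse", measure_species_pulse(1253, 2504, seed = 11))
  expect_lt(abs(m$df1_hz / 1253 - 1), 0.005)
  expect_lt(abs(m$df2_hz / 2504 - 1), 0.005)
})

test_that("a single tone yields DF2 absent and noise yields a flag", {
  fs <- 44100
  t <- seq(0, 0.2, by = 1 / fs)
  ps1 <- power_spectrum(sin(2 * pi * 1500 * t), sample_rate = fs)
  r1 <- find_dominant_frequencies(ps1)
  expect_true(r1$single_band)
  expect_true(is.na(r1$df2_hz))
  expect_equal(r1$df1_hz, 1500, tolerance = 1)
  set.seed(31)
  psn <- power_spectrum(rnorm(8820), sample_rate = fs)
  rn <- find_dominant_frequencies(psn)
  expect_true(rn$flagged)
  expect_true(is.na(rn$df1_hz))
})

test_that("Q matches the analytic Lorentzian bandwidth", {
  # damped sinusoid e^(-lambda t) sin(2 pi f0 t): one-sided power spectrum
  # is Lorentzian with -6 dB full width sqrt(10^0.6 - 1) * lambda / pi
  f0 <- 1591; q_target <- 16.6
  lambda <- pi * f0 / (sqrt(10^0.6 - 1) * q_target)
  fs <- 44100
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * f0 * t) * exp(-lambda * t)
  ps <- power_spectrum(x, pad_factor = 4, sample_rate = fs,
                       window = "rect")
  q <- q_value(ps, f0)
  # independent numeric oracle: -6 dB crossings of the closed-form
  # Lorentzian evaluated on a fine grid
  fgrid <- seq(f0 - 400, f0 + 400, by = 0.01)
  lor <- 1 / (lambda^2 + (2 * pi * (fgrid - f0))^2)
  db <- 10 * log10(lor)
  above <- fgrid[db > max(db) - 6]
  q_oracle <- f0 / (max(above) - min(above))
  expect_lt(abs(q / q_oracle - 1), 0.05)
  expect_equal(q_oracle, q_target, tolerance = 0.01)
  # monotonicity: slower decay -> narrower peak -> larger Q
  x2 <- sin(2 * pi * f0 * t) * exp(-lambda / 2 * t)
  q2 <- q_value(power_spectrum(x2, pad_factor = 4, sample_rate = fs,
                               window = "rect"), f0)
  expect_gt(q2, q)
})

test_that("dyad ratios reproduce the published examples", {
  expect_equal(dyad_ratio(1253, 2504)$ratio_2dp, 2.00)
  expect_equal(dyad_ratio(1000, 1000 * 1.0)$ratio_2dp, 1.00)
  expect_equal(dyad_ratio(929, 1387)$ratio_2dp, 1.49)
  expect_error(dyad_ratio(0, 100), "positive")
  expect_error(dyad_ratio(1000, NA), "absent")
})

test_that("the ratio is invariant to amplitude scaling", {
  cs <- call_spec(2043, 2715, n_fast = 1, n_slow = 0, pulse_rate_fast = 1,
                  pulse_dur_ms = 300, decay = 6, amp_pa = 0.1,
                  noise_sd_pa = 0)
  m1 <- measure_dyad(segment_pulses(synth_advertisement_call(cs, seed = 3))[[1]])
  cs$amp_pa <- 10  # 100x playback gain
  m2 <- measure_dyad(segment_pulses(synth_advertisement_call(cs, seed = 3))[[1]])
  expect_equal(m1$ratio, m2$ratio, tolerance = 1e-6)
})

test_that("interval classification matches the published examples", {
  expect_equal(classify_interval(1.33), "Perfect 4th")
  expect_equal(classify_interval(1.17), "Non-consonant")
  expect_equal(classify_interval(1.50), "Perfect 5th")
  expect_equal(classify_interval(1.00), "Non-consonant")
})

test_that("the classifier reproduces every published species label", {
  t1 <- xenopus_table1()
  cl <- t1[!is.na(t1$ratio), ]
  expect_equal(nrow(cl), 19)
  expect_equal(classify_interval(cl$ratio), cl$interval)
})

test_that("species summaries are means of per-male means", {
  one <- data.frame(species = "X. test", male = "m1",
                    df1_hz = 1000, df2_hz = 1330, q1 = 10, q2 = 12)
  s1 <- summarize_species(one)
  expect_equal(s1$df1_hz, 1000)
  expect_equal(s1$ratio, 1.33)
  expect_equal(s1$interval, "Perfect 4th")
  # three males with identical calls: SE 0
  same <- do.call(rbind, lapply(c("m1", "m2", "m3"), function(m)
    transform(one, male = m)))
  s3 <- summarize_species(same)
  expect_equal(s3$n_males, 3)
  expect_equal(s3$ratio_se, 0)
  # per-male means first: an unbalanced design must not weight by call count
  unb <- rbind(
    data.frame(species = "X. test", male = "m1",
               df1_hz = c(1000, 1000, 1000), df2_hz = c(1200, 1200, 1200),
               q1 = 10, q2 = 12),
    data.frame(species = "X. test", male = "m2",
               df1_hz = 1100, df2_hz = 1500, q1 = 10, q2 = 12))
  su <- summarize_species(unb)
  expect_equal(su$df1_hz, mean(c(1000, 1100)))
})

test_that("synthetic males around published means recover the species row", {
  set.seed(17)
  calls <- do.call(rbind, lapply(1:3, function(male) {
    do.call(rbind, lapply(1:3, function(call) {
      cs <- call_spec(2043 * exp(rnorm(1, 0, 0.01)),
                      2715 * exp(rnorm(1, 0, 0.01)),
                      n_fast = 3, n_slow = 0, pulse_dur_ms = 100,
                      pulse_rate_fast = 5, decay = 15)
      trc <- synth_advertisement_call(cs, seed = male * 10 + call)
      m <- measure_dyad(segment_pulses(trc)[[2]])
      transform(m, species = "X. amieti-like", male = paste0("m", male))
    }))
  }))
  s <- summarize_species(calls)
  expect_equal(s$ratio, 2715 / 2043, tolerance = 0.02)
  expect_equal(s$interval, "Perfect 4th")
  expect_equal(s$df1_hz, 2043, tolerance = 0.02)
})
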