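# analytic-signal magnitude envelope via the frequency-domain Hilbert
# transform
.envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Locate sound pulses in a recording and cut analysis segments
#'
#' Pulses are found where the smoothed magnitude envelope (analytic signal)
#' exceeds a threshold; nearby super-threshold runs are merged so the beat
#' minima of a two-tone pulse do not split it. The initial attack of each
#' pulse (`attack_ms`) is excluded from the analysis segment because it is
#' more broadband than the sustained portion.
#'
#' @param trace a `pressure_trace`.
#' @param attack_ms attack duration dropped from each pulse start, ms.
#' @param threshold_pa envelope threshold, Pa; default is the larger of 10%
#'   of the envelope maximum and 4x a robust noise estimate.
#' @param min_dur_ms minimum pulse duration, ms.
#' @param merge_gap_ms sub-threshold gaps shorter than this are bridged, ms.
#' @param smooth_ms envelope smoothing window, ms.
#' @return A list of `pulse_segment` objects (`samples`, `sample_rate`,
#'   `t_onset`, `attack_excluded = TRUE`), empty (with a warning) when no
#'   pulse is found. Segments shorter than 64 samples after attack exclusion
#'   are dropped.
#' @export
segment_pulses <- function(trace, attack_ms = 2, threshold_pa = NULL,
                           min_dur_ms = 2, merge_gap_ms = 3, smooth_ms = 3) {
  stopifnot(inherits(trace, "pressure_trace"))
  fs <- trace$sample_rate
  env <- .envelope(trace$samples)
  nw <- max(1L, round(smooth_ms * 1e-3 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / nw, nw), sides = 2))
  env[is.na(env)] <- 0
  if (is.null(threshold_pa)) {
    # noise scale from the quietest 5% of the envelope (Rayleigh q05 =
    # 0.320 sigma); valid as long as the trace is not sound for >95% of
    # its duration
    sigma <- stats::quantile(env, 0.05, names = FALSE) / 0.320
    threshold_pa <- max(4 * sigma, 0.1 * max(env))
  }
  above <- env > threshold_pa
  if (!any(above)) {
    warning("no pulses found")
    return(list())
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # bridge short gaps
  gap <- round(merge_gap_ms * 1e-3 * fs)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] <= gap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  keep <- (merged$end - merged$start + 1) >= round(min_dur_ms * 1e-3 * fs)
  merged <- merged[keep, , drop = FALSE]
  na <- round(attack_ms * 1e-3 * fs)
  env_raw <- .envelope(trace$samples)
  segs <- lapply(seq_len(nrow(merged)), function(i) {
    # refine the onset on the unsmoothed envelope: the smoothed crossing is
    # biased late by up to half the smoothing window
    s0 <- max(1L, merged$start[i] - nw)
    hit <- which(env_raw[s0:merged$end[i]] > threshold_pa)
    start <- if (length(hit)) s0 + hit[1] - 1L else merged$start[i]
    i0 <- start + na
    i1 <- merged$end[i]
    if (i1 - i0 + 1 < 64) return(NULL)
    structure(list(samples = trace$samples[i0:i1], sample_rate = fs,
                   t_onset = (start - 1) / fs,
                   attack_excluded = TRUE),
              class = "pulse_segment")
  })
  segs[!vapply(segs, is.null, logical(1))]
}

#' Power spectrum of a pulse segment
#'
#' Hann-windowed, zero-padded magnitude-squared spectrum. Zero-padding
#' (`pad_factor`) refines the frequency grid for peak interpolation without
#' adding information. Parseval's identity holds for the underlying FFT:
#' the band-integrated power (one-sided, doubled away from DC/Nyquist,
#' divided by `nfft`) equals the energy of the windowed signal.
#'
#' @param seg a `pulse_segment`, or a numeric vector with `sample_rate`.
#' @param pad_factor zero-padding factor (>= 1).
#' @param sample_rate required when `seg` is a bare numeric vector.
#' @param window `"hann"` (default, for call pulses cut from a recording) or
#'   `"rect"` (appropriate for a fully decayed transient, whose spectrum is
#'   then unbiased by the taper).
#' @return A data.frame of class `power_spectrum` (`freq_hz`, `power`, `db`)
#'   with attributes `nfft`, `sample_rate`, `n`, `windowed_energy`.
#' @export
power_spectrum <- function(seg, pad_factor = 4, sample_rate = NULL,
                           window = c("hann", "rect")) {
  window <- match.arg(window)
  if (inherits(seg, "pulse_segment")) {
    x <- seg$samples; fs <- seg$sample_rate
  } else {
    x <- as.numeric(seg); fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for a bare vector")
  }
  n <- length(x)
  if (n < 64) stop("segment too short (need >= 64 samples)")
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  else rep(1, n)
  xw <- x * w
  nfft <- 2^ceiling(log2(n * max(1, pad_factor)))
  X <- stats::fft(c(xw, numeric(nfft - n)))
  half <- seq_len(nfft / 2 + 1)
  p <- Mod(X[half])^2
  out <- data.frame(freq_hz = (half - 1) * fs / nfft, power = p,
                    db = 10 * log10(pmax(p, .Machine$double.xmin)))
  structure(out, nfft = nfft, sample_rate = fs, n = n,
            windowed_energy = sum(xw^2),
            class = c("power_spectrum", "data.frame"))
}

# parabolic refinement of a spectral peak at bin i (dB scale);
# returns c(freq, db)
.refine_peak <- function(ps, i) {
  dfreq <- ps$freq_hz[2] - ps$freq_hz[1]
  if (i <= 1 || i >= nrow(ps)) return(c(ps$freq_hz[i], ps$db[i]))
  ym <- ps$db[i - 1]; y0 <- ps$db[i]; yp <- ps$db[i + 1]
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den >= 0) return(c(ps$freq_hz[i], y0))
  d <- (ym - yp) / (2 * den)
  c(ps$freq_hz[i] + d * dfreq, y0 - (ym - yp) * d / 4)
}

#' Find the dominant frequencies of a spectrum
#'
#' Picks the two most prominent spectral peaks (topographic prominence on the
#' dB spectrum) separated by at least `min_sep_hz`, refines each by parabolic
#' interpolation, and returns the lower as DF1 and the higher as DF2. When
#' only one peak passes the prominence and level criteria the result is a
#' single-band measurement (DF2 absent) — the outcome seen after disrupting
#' the elastic-cartilage septa. When more than two comparable sustained peaks
#' are present the measurement is flagged as a harmonic stack.
#'
#' @param ps a `power_spectrum`.
#' @param min_sep_hz minimum separation between the two peaks, Hz.
#' @param prominence_db minimum peak prominence, dB.
#' @param floor_db minimum height above the median spectrum level, dB
#'   (rejects noise peaks).
#' @param max_below_peak_db a second peak must lie within this many dB of
#'   the strongest to count as a dominant frequency; window sidelobes and
#'   minor harmonics sit far lower.
#' @param band analysis band `c(low, high)`, Hz.
#' @param stack_within_db peaks within this many dB of the strongest count
#'   as comparable for the harmonic-stack flag.
#' @return A list: `df1_hz`, `df2_hz` (NA when absent), `n_peaks`,
#'   `single_band`, `harmonic_stack`, `flagged` (TRUE when no credible peak),
#'   and the candidate `peaks` data.frame.
#' @export
find_dominant_frequencies <- function(ps, min_sep_hz = 100,
                                      prominence_db = 6, floor_db = 15,
                                      max_below_peak_db = 20,
                                      band = c(100, Inf),
                                      stack_within_db = 10) {
  stopifnot(inherits(ps, "power_spectrum"))
  sel <- ps$freq_hz >= band[1] & ps$freq_hz <= band[2]
  sub <- ps[sel, ]
  db <- sub$db
  n <- length(db)
  i_max <- which(db[2:(n - 1)] > db[1:(n - 2)] &
                   db[2:(n - 1)] >= db[3:n]) + 1L
  if (!length(i_max))
    return(list(df1_hz = NA, df2_hz = NA, n_peaks = 0L, single_band = FALSE,
                harmonic_stack = FALSE, flagged = TRUE,
                peaks = data.frame()))
  prominence <- vapply(i_max, function(i) {
    h <- db[i]
    left <- db[seq_len(i - 1)]
    hi_l <- which(left > h)
    base_l <- min(left[seq(from = if (length(hi_l)) max(hi_l) else 1,
                           to = i - 1)])
    right <- db[(i + 1):n]
    hi_r <- which(right > h)
    base_r <- min(right[seq_len(if (length(hi_r)) min(hi_r) else n - i)])
    h - max(base_l, base_r)
  }, numeric(1))
  level_ok <- db[i_max] >= stats::median(ps$db) + floor_db
  cand <- data.frame(bin = i_max, freq_hz = sub$freq_hz[i_max],
                     db = db[i_max], prominence = prominence)[
                       prominence >= prominence_db & level_ok, ]
  if (nrow(cand))
    cand <- cand[cand$db >= max(cand$db) - max_below_peak_db, ]
  if (!nrow(cand))
    return(list(df1_hz = NA, df2_hz = NA, n_peaks = 0L, single_band = FALSE,
                harmonic_stack = FALSE, flagged = TRUE,
                peaks = data.frame()))
  cand <- cand[order(-cand$db), ]
  picked <- cand[1, ]
  for (i in seq_len(nrow(cand))[-1]) {
    if (all(abs(cand$freq_hz[i] - picked$freq_hz) >= min_sep_hz))
      picked <- rbind(picked, cand[i, ])
  }
  stack <- nrow(picked) >= 3 &&
    sum(picked$db >= picked$db[1] - stack_within_db) >= 3
  picked <- picked[seq_len(min(2, nrow(picked))), ]
  ref <- t(vapply(picked$bin, function(b)
    .refine_peak(sub, b), numeric(2)))
  freqs <- sort(ref[, 1])
  if (length(freqs) == 1)
    list(df1_hz = freqs[1], df2_hz = NA, n_peaks = nrow(cand),
         single_band = TRUE, harmonic_stack = stack, flagged = FALSE,
         peaks = cand)
  else
    list(df1_hz = freqs[1], df2_hz = freqs[2], n_peaks = nrow(cand),
         single_band = FALSE, harmonic_stack = stack, flagged = FALSE,
         peaks = cand)
}

#' Q-value of a spectral peak
#'
#' `Q = f_peak / (f_hi - f_lo)` where `f_hi` and `f_lo` are the crossings,
#' nearest the peak on either side, of the level 6 dB below the
#' (parabolically refined) peak, linearly interpolated between bins.
#'
#' @param ps a `power_spectrum`.
#' @param peak_hz peak frequency, Hz.
#' @param drop_db bandwidth criterion below the peak, dB.
#' @return The Q value, or NA (with a warning) when a -6 dB point is not
#'   bracketed within the spectrum.
#' @export
q_value <- function(ps, peak_hz, drop_db = 6) {
  stopifnot(inherits(ps, "power_spectrum"), peak_hz > 0)
  i <- which.min(abs(ps$freq_hz - peak_hz))
  # climb to the local maximum in case peak_hz sits on a shoulder
  while (i > 1 && ps$db[i - 1] > ps$db[i]) i <- i - 1
  while (i < nrow(ps) && ps$db[i + 1] > ps$db[i]) i <- i + 1
  ref <- .refine_peak(ps, i)
  target <- ref[2] - drop_db
  cross <- function(dir) {
    j <- i
    while (j + dir >= 1 && j + dir <= nrow(ps) && ps$db[j + dir] > target)
      j <- j + dir
    if (j + dir < 1 || j + dir > nrow(ps)) return(NA_real_)
    f1 <- ps$freq_hz[j]; f2 <- ps$freq_hz[j + dir]
    d1 <- ps$db[j]; d2 <- ps$db[j + dir]
    f1 + (target - d1) * (f2 - f1) / (d2 - d1)
  }
  f_lo <- cross(-1L); f_hi <- cross(+1L)
  if (is.na(f_lo) || is.na(f_hi)) {
    warning("-", drop_db, " dB point not bracketed; Q undefined")
    return(NA_real_)
  }
  ref[1] / (f_hi - f_lo)
}

#' DF2/DF1 dyad ratio
#'
#' @param df1_hz,df2_hz the two dominant frequencies, Hz (`df1 < df2`).
#' @return A list with `ratio` (full precision) and `ratio_2dp` (rounded to
#'   two decimals, the published precision).
#' @export
dyad_ratio <- function(df1_hz, df2_hz) {
  if (is.na(df1_hz) || df1_hz <= 0) stop("DF1 must be positive")
  if (is.na(df2_hz)) stop("DF2 absent: no ratio")
  r <- df2_hz / df1_hz
  list(ratio = r, ratio_2dp = round(r, 2))
}

#' Classify a dyad ratio as a musical interval
#'
#' Assigns the nearest of the five small-integer candidate ratios (2:1
#' Octave, 3:2 Perfect 5th, 4:3 Perfect 4th, 5:4 Major Third, 6:5 Minor
#' Third) when the ratio lies within the tolerance of it, else
#' "Non-consonant". The tolerance is proportional
#' (`|ratio / candidate - 1| <= tolerance`): 2% of the interval, which is
#' uniform across the candidate range where an absolute band would tighten
#' from 1.7% of a minor third to 1% of an octave. Classification is meant
#' for ratios at the published two-decimal precision.
#'
#' @param ratio dyad ratio(s), >= 1.
#' @param tolerance proportional tolerance.
#' @param candidates named numeric vector of candidate ratios.
#' @return A character vector of interval labels.
#' @export
classify_interval <- function(ratio, tolerance = 0.02,
                              candidates = c(Octave = 2 / 1,
                                             `Perfect 5th` = 3 / 2,
                                             `Perfect 4th` = 4 / 3,
                                             `Major Third` = 5 / 4,
                                             `Minor Third` = 6 / 5)) {
  stopifnot(all(ratio >= 1, na.rm = TRUE))
  vapply(ratio, function(r) {
    if (is.na(r)) return(NA_character_)
    dev <- abs(r / candidates - 1)
    i <- which.min(dev)
    if (dev[i] <= tolerance * (1 + 1e-9)) names(candidates)[i]
    else "Non-consonant"
  }, character(1))
}

#' Full dyad measurement of one pulse segment
#'
#' Spectrum, dominant frequencies, Q-values, ratio and interval in one step.
#'
#' @param seg a `pulse_segment`.
#' @param pad_factor zero-padding for the spectrum.
#' @param ... passed to [find_dominant_frequencies()].
#' @return A one-row data.frame: `df1_hz`, `df2_hz`, `q1`, `q2`, `ratio`,
#'   `ratio_2dp`, `interval`, `single_band`, `harmonic_stack`, `flagged`.
#' @export
measure_dyad <- function(seg, pad_factor = 4, ...) {
  ps <- power_spectrum(seg, pad_factor = pad_factor)
  df <- find_dominant_frequencies(ps, ...)
  q1 <- if (!is.na(df$df1_hz)) q_value(ps, df$df1_hz) else NA_real_
  q2 <- if (!is.na(df$df2_hz)) q_value(ps, df$df2_hz) else NA_real_
  if (!is.na(df$df1_hz) && !is.na(df$df2_hz)) {
    dr <- dyad_ratio(df$df1_hz, df$df2_hz)
    interval <- classify_interval(dr$ratio_2dp)
    ratio <- dr$ratio; ratio_2dp <- dr$ratio_2dp
  } else {
    ratio <- NA_real_; ratio_2dp <- NA_real_; interval <- NA_character_
  }
  data.frame(df1_hz = df$df1_hz, df2_hz = df$df2_hz, q1 = q1, q2 = q2,
             ratio = ratio, ratio_2dp = ratio_2dp, interval = interval,
             single_band = df$single_band,
             harmonic_stack = df$harmonic_stack, flagged = df$flagged)
}

#' Species-level dyad summary
#'
#' Computes, from per-call dyad measurements grouped by male, the published
#' summary: per-male means first, then the species mean and standard error
#' over males; the interval label is classified from the species mean ratio
#' rounded to two decimals.
#'
#' @param measurements data.frame with columns `species`, `male`, `df1_hz`,
#'   `df2_hz`, `q1`, `q2` and optionally `ratio` (recomputed from the
#'   frequencies when absent); one row per call.
#' @return A Table-1-shaped data.frame: one row per species with `n_males`,
#'   mean and SE of DF1, Q1, DF2, Q2 and the ratio, plus the `interval`.
#' @export
summarize_species <- function(measurements) {
  stopifnot(all(c("species", "male", "df1_hz", "df2_hz") %in%
                  names(measurements)))
  if (!nrow(measurements)) stop("no measurements")
  m <- measurements
  if (is.null(m$ratio)) m$ratio <- m$df2_hz / m$df1_hz
  for (col in c("q1", "q2")) if (is.null(m[[col]])) m[[col]] <- NA_real_
  vars <- c("df1_hz", "q1", "df2_hz", "q2", "ratio")
  per_male <- stats::aggregate(m[vars],
                               by = list(species = m$species, male = m$male),
                               FUN = mean, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(per_male, per_male$species),
                               function(d) {
    n <- nrow(d)
    mu <- vapply(d[vars], mean, numeric(1))
    se <- vapply(d[vars], function(v)
      if (n > 1) stats::sd(v) / sqrt(n) else NA_real_, numeric(1))
    data.frame(species = d$species[1], n_males = n,
               df1_hz = mu["df1_hz"], df1_se = se["df1_hz"],
               q1 = mu["q1"], q1_se = se["q1"],
               df2_hz = mu["df2_hz"], df2_se = se["df2_hz"],
               q2 = mu["q2"], q2_se = se["q2"],
               ratio = mu["ratio"], ratio_se = se["ratio"],
               interval = classify_interval(round(mu["ratio"], 2)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
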