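#' Extract a tracking template from a frame stack
#'
#' Cuts a square intensity patch around a bead in a reference frame. The
#' patch and its reference centre seed the cross-correlation tracker. The
#' bead's subpixel offset inside the patch (thresholded darkness centroid)
#' is stored so tracked positions are absolute, not merely relative to the
#' integer patch centre.
#'
#' @param stack a `frame_stack`.
#' @param frame_idx reference frame (1-based); a vector of frames over which
#'   the bead is at rest averages the patch, reducing template noise.
#' @param center_px integer `c(x, y)` pixel position of the bead centre
#'   (x = column, y = row).
#' @param half_size_px half-width of the template window, px.
#' @return A list of class `bead_template` with `patch`, `center_px`,
#'   `center_offset_px` and `half_size_px`.
#' @export
extract_template <- function(stack, frame_idx, center_px, half_size_px) {
  stopifnot(inherits(stack, "frame_stack"), half_size_px >= 1)
  d <- dim(stack$frames)
  cx <- round(center_px[1]); cy <- round(center_px[2]); h <- half_size_px
  if (cx - h < 1 || cx + h > d[2] || cy - h < 1 || cy + h > d[1])
    stop("template window clipped by the frame boundary")
  patch <- stack$frames[(cy - h):(cy + h), (cx - h):(cx + h), frame_idx,
                        drop = FALSE]
  patch <- apply(patch, c(1, 2), mean)
  dark <- matrix(pmax(0, stats::median(patch) - patch), nrow(patch))
  dark[dark < 0.2 * max(dark)] <- 0
  off <- c(x = 0, y = 0)
  if (sum(dark) > 0) {
    rel <- (-h):h
    off <- c(x = sum(colSums(dark) * rel) / sum(dark),
             y = sum(rowSums(dark) * rel) / sum(dark))
  }
  structure(list(patch = patch, center_px = c(x = cx, y = cy),
                 center_offset_px = off, half_size_px = h),
            class = "bead_template")
}

# normalized cross-correlation between a (zero-mean-normalized) template and
# a same-sized patch
.ncc <- function(t0, t_ss, patch) {
  p0 <- patch - mean(patch)
  den <- sqrt(t_ss * sum(p0 * p0))
  if (den <= 0) return(0)
  sum(t0 * p0) / den
}

# per-axis quadratic refinement of a correlation peak: offset of the vertex
# of the parabola through (-1, ym), (0, y0), (1, yp)
.quad_refine <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den >= 0) return(0)
  d <- (ym - yp) / (2 * den)
  max(-0.5, min(0.5, d))
}

#' Track a bead through a frame stack at subpixel precision
#'
#' Per frame, the template is cross-correlated (normalized, zero-mean)
#' against patches shifted within `search_radius_px` of the position found in
#' the previous frame. The integer argmax is refined by a per-axis quadratic
#' fit of the 3x3 correlation peak neighbourhood. Frames whose peak score
#' falls below `score_floor` are flagged as lost, interpolated linearly, and
#' reported with a warning — never silently.
#'
#' @param stack a `frame_stack`.
#' @param tpl a `bead_template` from [extract_template()].
#' @param search_radius_px search radius around the previous position, px.
#' @param score_floor minimum acceptable correlation peak score.
#' @return A trajectory data.frame: `frame`, `t_s`, `x_um`, `y_um`, `score`,
#'   `lost`. Positions are in micrometres in the stack's world coordinates
#'   (`origin_um` + pixel * `px_size_um`).
#' @export
track_bead <- function(stack, tpl, search_radius_px = 4, score_floor = 0.5) {
  stopifnot(inherits(stack, "frame_stack"), inherits(tpl, "bead_template"))
  d <- dim(stack$frames)
  n <- d[3]; h <- tpl$half_size_px; r <- search_radius_px
  t0 <- tpl$patch - mean(tpl$patch)
  t_ss <- sum(t0 * t0)
  px <- numeric(n); py <- numeric(n); score <- numeric(n)
  cx <- tpl$center_px[["x"]]; cy <- tpl$center_px[["y"]]
  for (i in seq_len(n)) {
    djs <- (-r):r; dis <- (-r):r
    djs <- djs[cx + djs - h >= 1 & cx + djs + h <= d[2]]
    dis <- dis[cy + dis - h >= 1 & cy + dis + h <= d[1]]
    if (!length(djs) || !length(dis))
      stop("search window left the frame at frame ", i)
    sc <- matrix(-Inf, length(dis), length(djs))
    fr <- stack$frames[, , i]
    for (a in seq_along(dis)) for (b in seq_along(djs)) {
      yy <- cy + dis[a]; xx <- cx + djs[b]
      sc[a, b] <- .ncc(t0, t_ss,
                       fr[(yy - h):(yy + h), (xx - h):(xx + h)])
    }
    ij <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    bi <- ij[1]; bj <- ij[2]
    dx <- if (bj > 1 && bj < ncol(sc))
      .quad_refine(sc[bi, bj - 1], sc[bi, bj], sc[bi, bj + 1]) else 0
    dy <- if (bi > 1 && bi < nrow(sc))
      .quad_refine(sc[bi - 1, bj], sc[bi, bj], sc[bi + 1, bj]) else 0
    px[i] <- cx + djs[bj] + dx
    py[i] <- cy + dis[bi] + dy
    score[i] <- sc[bi, bj]
    cx <- cx + djs[bj]; cy <- cy + dis[bi]  # follow the bead
  }
  lost <- score < score_floor
  if (any(lost)) {
    warning(sum(lost), " frame(s) below score floor ", score_floor,
            "; positions interpolated linearly")
    ok <- which(!lost)
    if (length(ok) < 2) stop("too few confidently tracked frames")
    px[lost] <- stats::approx(ok, px[ok], xout = which(lost), rule = 2)$y
    py[lost] <- stats::approx(ok, py[ok], xout = which(lost), rule = 2)$y
  }
  off <- tpl$center_offset_px %||% c(x = 0, y = 0)
  data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / stack$frame_rate,
             x_um = (px + off[["x"]] - 1) * stack$px_size_um +
               stack$origin_um[1],
             y_um = (py + off[["y"]] - 1) * stack$px_size_um +
               stack$origin_um[2],
             score = score, lost = lost)
}

#' Gap width from a pair of bead trajectories
#'
#' The arytenoid gap width `w(t)` is the summed displacement of the two disc
#' markers from their resting positions, projected perpendicular to the
#' laryngeal midline and signed positive when a marker moves away from the
#' midline. At rest `w = 0`.
#'
#' @param left,right trajectory data.frames (`frame`, `t_s`, `x_um`,
#'   `y_um`) over a common frame range.
#' @param midline image axis the midline runs along: `"vertical"` (beads
#'   separate along x) or `"horizontal"` (along y).
#' @param rest_frames indices of frames known to precede the first stimulus;
#'   their mean position defines the rest baseline. Required.
#' @return A kinematic-series data.frame (`frame`, `t_s`, `w_um`) with the
#'   frame rate in `attr(, "frame_rate")`.
#' @export
compute_gap_width <- function(left, right,
                              midline = c("vertical", "horizontal"),
                              rest_frames = NULL) {
  midline <- match.arg(midline)
  if (is.null(rest_frames) || !length(rest_frames))
    stop("a rest interval before the first stimulus is required")
  n <- min(nrow(left), nrow(right))
  left <- left[seq_len(n), ]; right <- right[seq_len(n), ]
  coord <- if (midline == "vertical") "x_um" else "y_um"
  rl <- mean(left[[coord]][rest_frames])
  rr <- mean(right[[coord]][rest_frames])
  mid <- (rl + rr) / 2
  w <- sign(rl - mid) * (left[[coord]] - rl) +
    sign(rr - mid) * (right[[coord]] - rr)
  dt <- stats::median(diff(left$t_s))
  structure(data.frame(frame = left$frame, t_s = left$t_s, w_um = w),
            frame_rate = 1 / dt)
}

#' Velocity and acceleration of a kinematic series
#'
#' Smooths the gap-width series with a moving polynomial (Savitzky-Golay)
#' fit, then differentiates by central finite differences; the velocity is
#' smoothed again with the same moving fit before the second differentiation,
#' since double differentiation of raw tracking jitter would otherwise
#' dominate the acceleration. Acceleration is reported both in m/s^2 and in
#' g (1 g = 9.82 m/s^2). The smoothing window is exposed because
#' acceleration is noise-amplifying.
#'
#' @param ks kinematic series from [compute_gap_width()] (uniform sampling).
#' @param smooth_window moving-fit window length, frames (odd; `1` disables
#'   smoothing).
#' @param smooth_order polynomial order of the moving fit.
#' @param g_m_s2 the value of 1 g used for conversion.
#' @return The input data.frame with added `v_mm_s`, `a_m_s2`, `a_g`.
#' @export
differentiate_series <- function(ks, smooth_window = 5, smooth_order = 2,
                                 g_m_s2 = 9.82) {
  stopifnot(is.data.frame(ks), all(c("t_s", "w_um") %in% names(ks)))
  n <- nrow(ks)
  if (smooth_window > n) stop("smoothing window longer than the series")
  dts <- diff(ks$t_s)
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("series must be uniformly sampled")
  dt <- dts[1]
  smooth <- function(x) if (smooth_window >= 3)
    signal::sgolayfilt(x, p = smooth_order, n = smooth_window) else x
  cdiff <- function(x) {
    d <- numeric(length(x))
    d[2:(length(x) - 1)] <- (x[3:length(x)] - x[1:(length(x) - 2)]) / (2 * dt)
    d[1] <- d[2]; d[length(x)] <- d[length(x) - 1]
    d
  }
  w <- smooth(ks$w_um)
  v_um_s <- cdiff(w)
  a_um_s2 <- cdiff(smooth(v_um_s))
  ks$w_smooth_um <- w
  ks$v_mm_s <- v_um_s * 1e-3
  ks$a_m_s2 <- a_um_s2 * 1e-6
  ks$a_g <- ks$a_m_s2 / g_m_s2
  attr(ks, "frame_rate") <- 1 / dt
  ks
}
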