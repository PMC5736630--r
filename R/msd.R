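#' Time-averaged mean-squared displacement of one trajectory
#'
#' Overlapping-origin estimator: `MSD(k) = mean over origins t of
#' (x(t+k) - x(t))^2 + (y(t+k) - y(t))^2`, with lags reported in seconds via
#' the acquisition rate. Frames missing from the trajectory (gap-closed
#' links) simply contribute no origin pairs.
#'
#' @param trajectory data.frame with columns `frame`, `x`, `y` (um) for one
#'   particle.
#' @param fps Frames per second.
#' @param max_lag_frames Largest lag, in frames; truncated (with a message)
#'   to the trajectory span minus one when too large.
#' @return An `msd_curve`: data.frame with columns `lag_s`, `msd_um2`,
#'   `n_traj` (here the number of origin pairs), and attribute `fps`.
#' @export
trajectory_msd <- function(trajectory, fps, max_lag_frames = 100L) {
  if (nrow(trajectory) < 2L) stop("trajectory needs at least 2 points")
  span <- diff(range(trajectory$frame))
  if (max_lag_frames > span) {
    message("max_lag_frames truncated to trajectory span (", span, ")")
    max_lag_frames <- span
  }
  m <- msd_by_lag(trajectory, max_lag_frames)
  msd_curve(lag_s = seq_len(max_lag_frames) / fps, msd = m$msd,
            n = m$npairs, fps = fps)
}

# Per-lag mean squared displacement and pair counts for one trajectory,
# frame-indexed with NA holes for gaps.
msd_by_lag <- function(trajectory, max_lag) {
  f0 <- min(trajectory$frame)
  n <- diff(range(trajectory$frame)) + 1L
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  idx <- trajectory$frame - f0 + 1L
  x[idx] <- trajectory$x; y[idx] <- trajectory$y
  msd <- numeric(max_lag); npairs <- integer(max_lag)
  for (k in seq_len(max_lag)) {
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    sq <- dx * dx + dy * dy
    ok <- !is.na(sq)
    npairs[k] <- sum(ok)
    msd[k] <- if (npairs[k]) mean(sq[ok]) else NA_real_
  }
  list(msd = msd, npairs = npairs)
}

msd_curve <- function(lag_s, msd, n, fps) {
  structure(data.frame(lag_s = lag_s, msd_um2 = msd, n_traj = n),
            fps = fps, class = c("msd_curve", "data.frame"))
}

#' Ensemble-averaged mean-squared displacement
#'
#' Computes the time-averaged MSD of every sufficiently long trajectory and
#' takes the unweighted mean across trajectories at each lag (each
#' trajectory counts once, regardless of length). The number of
#' trajectories contributing is recorded per lag.
#'
#' @param ensemble A [traj_ensemble()].
#' @param max_lag_frames Largest lag in frames (default 100, i.e. 1.67 s at
#'   60 fps).
#' @param min_traj_length Minimum number of points for a trajectory to enter
#'   the ensemble average (default 110, so the reference lag of 100 frames
#'   is estimated from at least 10 origins).
#' @return An `msd_curve` (columns `lag_s`, `msd_um2`, `n_traj`).
#' @export
ensemble_msd <- function(ensemble, max_lag_frames = 100L,
                         min_traj_length = 110L) {
  fps <- attr(ensemble, "fps")
  parts <- split(as.data.frame(ensemble)[c("frame", "x", "y")],
                 ensemble$particle)
  parts <- Filter(function(p) nrow(p) >= min_traj_length, parts)
  if (!length(parts))
    stop("no trajectory has at least min_traj_length = ", min_traj_length,
         " points")
  acc <- matrix(0, length(parts), max_lag_frames)
  for (i in seq_along(parts))
    acc[i, ] <- msd_by_lag(parts[[i]], max_lag_frames)$msd
  msd_curve(lag_s = seq_len(max_lag_frames) / fps,
            msd = colMeans(acc, na.rm = TRUE),
            n = colSums(!is.na(acc)), fps = fps)
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, %g-%g s, fps=%g\n", nrow(x),
              min(x$lag_s), max(x$lag_s), attr(x, "fps")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag_s, x$msd_um2, log = "xy",
                 xlab = "lag time (s)",
                 ylab = expression(paste(langle, Delta * r^2, rangle,
                                         " (", mu * m^2, ")")), ...)
}
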