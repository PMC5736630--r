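#' Ensemble drift correction
#'
#' Removes common-mode (advective) motion: for every consecutive frame
#' pair the mean x and y displacement over the trajectories spanning both
#' frames is computed, and that per-pair mean is subtracted from every
#' trajectory's displacement across the pair. Corrected positions are
#' rebuilt by cumulative summation from each trajectory's first frame, so
#' each trajectory's starting position is unchanged. Frame pairs spanned by
#' no trajectory contribute zero correction (reported via a message). A
#' step across a linking gap is corrected by the drift accumulated over the
#' skipped pairs.
#'
#' Note the finite-ensemble bias: with N independent particles the ensemble
#' mean contains 1/N of each particle's own motion, so correction shrinks
#' the MSD of truly independent motion by the factor (N-1)/N.
#'
#' @param ensemble A [traj_ensemble()].
#' @return The drift-corrected ensemble, with the cumulative drift series
#'   that was removed attached as attribute `drift_removed` (n_pairs+1 x 2).
#' @export
subtract_drift <- function(ensemble) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  if (nrow(ensemble) == 0L) stop("empty trajectory ensemble")
  if (n_trajectories(ensemble) == 1L)
    warning("drift correction with a single trajectory zeroes all of its ",
            "displacements")
  f0 <- min(ensemble$frame); f1 <- max(ensemble$frame)
  frames <- f0:f1
  npairs <- length(frames) - 1L

  df <- as.data.frame(ensemble)   # constructor guarantees (particle, frame) order
  same <- c(FALSE, df$particle[-1] == df$particle[-nrow(df)])
  # per consecutive-pair sums via tabulation over steps of exactly one frame
  step1 <- same & c(FALSE, diff(df$frame) == 1)
  pair_idx <- df$frame[step1] - f0               # 1-based pair id = idx
  sdx <- c(NA, diff(df$x))[step1]
  sdy <- c(NA, diff(df$y))[step1]
  cnt <- tabulate(pair_idx, nbins = npairs)
  mx <- ifelse(cnt > 0, tapply_sum(sdx, pair_idx, npairs) / pmax(cnt, 1), 0)
  my <- ifelse(cnt > 0, tapply_sum(sdy, pair_idx, npairs) / pmax(cnt, 1), 0)
  if (any(cnt == 0))
    message(sum(cnt == 0), " frame pair(s) spanned by no trajectory; ",
            "zero correction applied there")

  cum <- rbind(c(0, 0), cbind(cumsum(mx), cumsum(my)))  # indexed frame-f0+1
  idx <- ensemble$frame - f0 + 1L
  corr_x <- ensemble$x - cum[idx, 1]
  corr_y <- ensemble$y - cum[idx, 2]
  # re-anchor each trajectory at its original first position
  first <- !duplicated(ensemble$particle)
  off_x <- (ensemble$x - corr_x)[first]
  off_y <- (ensemble$y - corr_y)[first]
  pid <- match(ensemble$particle, ensemble$particle[first])
  out <- ensemble
  out$x <- corr_x + off_x[pid]
  out$y <- corr_y + off_y[pid]
  attr(out, "drift_removed") <- cum
  out
}

tapply_sum <- function(v, idx, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
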