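#' Simulate ground-truth probe trajectories
#'
#' Generates an ensemble of independent 2-D probe trajectories under the
#' dynamical model named in the configuration, then (in order) applies
#' optional reflecting boundaries, common-mode drift and localization noise.
#' The four models span the regimes a probe at a bacteria-laden interface can
#' display:
#'
#' * `brownian` — thermal diffusion: i.i.d. Gaussian increments with
#'   per-coordinate variance `2 D / fps` per frame; ensemble MSD `4 D t`.
#' * `fbm` — fractional Brownian motion per coordinate (Hurst `H`, variance
#'   coefficient `scale`); ensemble MSD `2 * scale * t^(2H)`, subdiffusive
#'   for `H < 1/2`. Sampled exactly by circulant embedding (Davies-Harte)
#'   with a Cholesky fallback.
#' * `prw` — persistent random walk: Ornstein-Uhlenbeck velocity with
#'   persistence time `tau_p` and speed scale `v`, integrated exactly over
#'   each frame; ensemble MSD `2 v^2 tau_p^2 (t/tau_p - 1 + exp(-t/tau_p))`,
#'   ballistic (slope 2) below `tau_p` and diffusive above. Mimics probes
#'   pushed along persistent paths by active swimmers.
#' * `arrested` — probes tethered to fixed anchors: Ornstein-Uhlenbeck
#'   position with equilibrium std `sigma_eq` per coordinate and relaxation
#'   `tau_r`; for `tau_r` well below the frame interval the MSD is flat at
#'   `4 sigma_eq^2`, the signature of an elastic film.
#'
#' @param config A [sim_config()].
#' @return A `ground_truth` object: a [traj_ensemble()] with attributes
#'   `config`, `regime` (true regime label), and `drift` (the n_frames x 2
#'   cumulative common-mode displacement actually applied, um).
#' @examples
#' cfg <- sim_config("brownian", n_particles = 5, n_frames = 100,
#'                   model_params = list(D = 0.15), seed = 7)
#' gt <- simulate_trajectories(cfg)
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$seed)
  np <- config$n_particles
  nf <- config$n_frames
  dt <- 1 / config$fps

  pos <- with_seed(seeds[1], switch(config$model,
    brownian = sim_steps_gaussian(np, nf,
                 sd = sqrt(2 * config$model_params$D * dt)),
    fbm = sim_fbm(np, nf, config$model_params$H,
                  config$model_params$scale, dt),
    prw = sim_prw(np, nf, config$model_params$v,
                  config$model_params$tau_p, dt),
    arrested = sim_arrested(np, nf, config$model_params$sigma_eq,
                            config$model_params$tau_r, dt)))

  origin <- with_seed(seeds[3], {
    lo <- 0.2 * config$box_size
    hi <- 0.8 * config$box_size
    if ((config$placement %||% "uniform") == "grid") {
      k <- ceiling(sqrt(np))
      site <- if (k == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = k)
      g <- expand.grid(x = site, y = site)[seq_len(np), ]
      jit <- if (k == 1L) 0.1 else 0.1 * diff(site[1:2])
      cbind(g$x + stats::runif(np, -jit, jit),
            g$y + stats::runif(np, -jit, jit))
    } else {
      cbind(stats::runif(np, lo, hi), stats::runif(np, lo, hi))
    }
  })
  pos$x <- pos$x + origin[pos$particle, 1]
  pos$y <- pos$y + origin[pos$particle, 2]

  if (isTRUE(config$reflect)) {
    pos$x <- reflect_coord(pos$x, config$box_size)
    pos$y <- reflect_coord(pos$y, config$box_size)
  }

  gt <- ground_truth(pos, config, drift = matrix(0, nf, 2))
  if (any(config$drift_velocity != 0)) {
    tgrid <- (seq_len(nf) - 1) * dt
    gt <- apply_drift(gt, cbind(config$drift_velocity[1] * tgrid,
                                config$drift_velocity[2] * tgrid))
  }

  if (config$localization_noise_sigma > 0) {
    gt_noise <- with_seed(seeds[2],
      stats::rnorm(2L * nrow(gt), sd = config$localization_noise_sigma))
    gt$x <- gt$x + gt_noise[seq_len(nrow(gt))]
    gt$y <- gt$y + gt_noise[nrow(gt) + seq_len(nrow(gt))]
  }
  gt
}

# Regime labels implied by the generating model; the analysis must recover
# these blindly from the trajectories.
true_regime <- function(config) {
  switch(config$model,
    brownian = "diffusive",
    prw = "superdiffusive",
    arrested = "elastic",
    fbm = {
      H <- config$model_params$H
      if (H < 0.5) "subdiffusive" else if (H > 0.5) "superdiffusive"
      else "diffusive"
    })
}

ground_truth <- function(pos, config, drift) {
  te <- traj_ensemble(pos, fps = config$fps)
  attr(te, "config") <- config
  attr(te, "regime") <- true_regime(config)
  attr(te, "drift") <- drift
  class(te) <- c("ground_truth", class(te))
  te
}

# Long-format positions from per-particle increment rows (np x (nf-1)).
cum_positions <- function(dx, dy) {
  np <- nrow(dx); nf <- ncol(dx) + 1L
  row_cumsum <- function(m)
    if (ncol(m) == 1L) m else t(apply(m, 1, cumsum))
  x <- cbind(0, row_cumsum(dx))
  y <- cbind(0, row_cumsum(dy))
  data.frame(particle = rep(seq_len(np), each = nf),
             frame = rep(0:(nf - 1L), np),
             x = as.vector(t(x)), y = as.vector(t(y)))
}

sim_steps_gaussian <- function(np, nf, sd) {
  dx <- matrix(stats::rnorm(np * (nf - 1L), sd = sd), np)
  dy <- matrix(stats::rnorm(np * (nf - 1L), sd = sd), np)
  cum_positions(dx, dy)
}

sim_fbm <- function(np, nf, H, scale, dt) {
  inc <- fgn_sample(2L * np, nf - 1L, H, scale, dt)
  cum_positions(inc[seq_len(np), , drop = FALSE],
                inc[np + seq_len(np), , drop = FALSE])
}

# Exact discrete integration of the OU-velocity persistent random walk.
# Per-coordinate stationary velocity variance v^2/2, so the 2-D MSD is
# 2 v^2 tau^2 (t/tau - 1 + exp(-t/tau)).
sim_prw <- function(np, nf, v, tau, dt) {
  sv2 <- v^2 / 2
  mu <- exp(-dt / tau)
  var_v <- sv2 * (1 - mu^2)
  var_x <- sv2 * tau * (2 * dt - tau * (3 - 4 * mu + mu^2))
  cov_vx <- sv2 * tau * (1 - mu)^2
  # conditional decomposition: draw dx given the velocity kick
  b <- if (var_v > 0) cov_vx / var_v else 0
  var_x_res <- max(var_x - b^2 * var_v, 0)

  one_coord <- function() {
    vel <- stats::rnorm(np, sd = sqrt(sv2))   # stationary initial velocity
    dxm <- matrix(0, np, nf - 1L)
    for (k in seq_len(nf - 1L)) {
      zv <- stats::rnorm(np, sd = sqrt(var_v))
      zx <- stats::rnorm(np, sd = sqrt(var_x_res))
      dxm[, k] <- vel * tau * (1 - mu) + b * zv + zx
      vel <- vel * mu + zv
    }
    dxm
  }
  dx <- one_coord(); dy <- one_coord()
  cum_positions(dx, dy)
}

# OU position about fixed anchors, stationary start; positions (not
# increments) are generated directly.
sim_arrested <- function(np, nf, sigma_eq, tau_r, dt) {
  mu <- exp(-dt / tau_r)
  sd_step <- sigma_eq * sqrt(1 - mu^2)
  one_coord <- function() {
    m <- matrix(0, np, nf)
    m[, 1] <- stats::rnorm(np, sd = sigma_eq)
    for (k in 2:nf) m[, k] <- m[, k - 1] * mu + stats::rnorm(np, sd = sd_step)
    m
  }
  x <- one_coord(); y <- one_coord()
  data.frame(particle = rep(seq_len(np), each = nf),
             frame = rep(0:(nf - 1L), np),
             x = as.vector(t(x)), y = as.vector(t(y)))
}

reflect_coord <- function(z, L) {
  z <- z %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}

#' Add common-mode drift to a ground-truth ensemble
#'
#' Adds the same per-frame displacement to every particle, leaving all
#' relative motion untouched. The true cumulative drift is recorded in the
#' `drift` attribute so tests can undo it exactly with [remove_drift()].
#'
#' @param truth A `ground_truth` object from [simulate_trajectories()].
#' @param drift An `n_frames x 2` matrix of cumulative common-mode
#'   displacement in um (row k = total drift of frame k relative to frame 1).
#' @return The shifted `ground_truth`.
#' @export
apply_drift <- function(truth, drift) {
  stopifnot(inherits(truth, "ground_truth"))
  nf <- attr(truth, "config")$n_frames
  drift <- as.matrix(drift)
  if (nrow(drift) != nf || ncol(drift) != 2L)
    stop("drift must be an n_frames x 2 matrix (got ",
         nrow(drift), " x ", ncol(drift), ")")
  idx <- truth$frame + 1L
  truth$x <- truth$x + drift[idx, 1]
  truth$y <- truth$y + drift[idx, 2]
  attr(truth, "drift") <- attr(truth, "drift") + drift
  truth
}

#' @rdname apply_drift
#' @export
remove_drift <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  drift <- attr(truth, "drift")
  idx <- truth$frame + 1L
  truth$x <- truth$x - drift[idx, 1]
  truth$y <- truth$y - drift[idx, 2]
  attr(truth, "drift") <- drift * 0
  truth
}
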