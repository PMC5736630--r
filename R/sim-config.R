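#' Simulation configuration for ground-truth trajectory generators
#'
#' Bundles the parameters shared by all trajectory simulators: the dynamical
#' model, ensemble size, acquisition rate, localization noise and common-mode
#' drift. Units are physical throughout: positions in micrometres, time in
#' seconds, rates in Hz.
#'
#' @param model One of `"brownian"`, `"fbm"`, `"prw"`, `"arrested"`.
#' @param n_particles Number of independent probe trajectories (>= 1).
#' @param n_frames Number of frames per trajectory (>= 2).
#' @param fps Acquisition rate in frames per second (> 0). Default 60,
#'   the rate of the video recordings the synthetic data emulate.
#' @param box_size Side of the square field of view in micrometres. Used by
#'   the renderer and for initial particle placement; trajectories themselves
#'   evolve on the unbounded plane unless `reflect = TRUE`.
#' @param reflect If `TRUE`, trajectories are reflected at the box walls
#'   (useful before rendering); default `FALSE` (unbounded plane).
#' @param seed Master integer seed. Dynamics noise, localization noise and
#'   initial placement each consume an independent stream derived from this
#'   seed (see Details), so identical configurations reproduce bit-identical
#'   trajectories.
#' @param localization_noise_sigma Standard deviation, in micrometres, of
#'   i.i.d. Gaussian localization noise added to every coordinate in every
#'   frame after the dynamics are simulated. Default 0 (no noise).
#' @param drift_velocity Length-2 numeric, common-mode drift velocity in
#'   micrometres per second (x, y). Default `c(0, 0)`.
#' @param placement Initial-position layout: `"uniform"` (random uniform
#'   over the central 60% of the box) or `"grid"` (jittered square lattice,
#'   guaranteeing initial separation — the layout to use before rendering
#'   when downstream tracking accuracy is being measured).
#' @param model_params Named list of model parameters:
#'   * brownian: `D` (diffusivity, um^2/s, >= 0);
#'   * fbm: `H` (Hurst exponent, 0 < H < 1) and `scale` (per-coordinate
#'     variance coefficient, um^2/s^(2H): Var x(t) = scale * t^(2H));
#'   * prw: `v` (speed scale, um/s; the ensemble MSD prefactor is 2 v^2
#'     tau_p^2) and `tau_p` (persistence time, s, > 0);
#'   * arrested: `sigma_eq` (equilibrium displacement std per coordinate,
#'     um, >= 0) and `tau_r` (relaxation time, s, > 0).
#'
#' @details
#' Seed splitting: the master seed initializes R's RNG once, from which three
#' sub-seeds (dynamics, localization noise, placement) are drawn with
#' `sample.int(.Machine$integer.max, 3)`. Each stage then re-seeds with its
#' own sub-seed, so e.g. switching localization noise on or off never changes
#' the underlying dynamics realization.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trajectories()]
#' @export
sim_config <- function(model = c("brownian", "fbm", "prw", "arrested"),
                       n_particles, n_frames, fps = 60,
                       box_size = 50, reflect = FALSE,
                       placement = c("uniform", "grid"),
                       seed = 1L,
                       localization_noise_sigma = 0,
                       drift_velocity = c(0, 0),
                       model_params = list()) {
  model <- match.arg(model)
  placement <- match.arg(placement)
  stopifnot(is.numeric(n_particles), length(n_particles) == 1L,
            is.numeric(n_frames), length(n_frames) == 1L)
  n_particles <- as.integer(n_particles)
  n_frames <- as.integer(n_frames)
  if (n_particles < 1L) stop("n_particles must be >= 1")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (!is.numeric(box_size) || box_size <= 0) stop("box_size must be > 0")
  if (!is.numeric(localization_noise_sigma) || localization_noise_sigma < 0)
    stop("localization_noise_sigma must be >= 0")
  if (length(drift_velocity) != 2L || !all(is.finite(drift_velocity)))
    stop("drift_velocity must be a finite length-2 vector (um/s)")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")

  p <- model_params
  check_pos <- function(x, name, strict = FALSE) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("model_params$%s must be a finite number", name))
    if (strict && x <= 0) stop(sprintf("model_params$%s must be > 0", name))
    if (!strict && x < 0) stop(sprintf("model_params$%s must be >= 0", name))
    as.numeric(x)
  }
  p <- switch(model,
    brownian = list(D = check_pos(p$D, "D")),
    fbm = {
      H <- check_pos(p$H, "H", strict = TRUE)
      if (H >= 1) stop("model_params$H must lie in (0, 1)")
      list(H = H, scale = check_pos(p$scale %||% 1, "scale"))
    },
    prw = list(v = check_pos(p$v, "v"),
               tau_p = check_pos(p$tau_p, "tau_p", strict = TRUE)),
    arrested = list(sigma_eq = check_pos(p$sigma_eq, "sigma_eq"),
                    tau_r = check_pos(p$tau_r %||% 1e-3, "tau_r",
                                      strict = TRUE))
  )

  structure(list(model = model, n_particles = n_particles,
                 n_frames = n_frames, fps = as.numeric(fps),
                 box_size = as.numeric(box_size),
                 reflect = isTRUE(reflect), placement = placement,
                 seed = seed,
                 localization_noise_sigma =
                   as.numeric(localization_noise_sigma),
                 drift_velocity = as.numeric(drift_velocity),
                 model_params = p),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> model=%s  %d particles x %d frames @ %g fps\n",
              x$model, x$n_particles, x$n_frames, x$fps))
  cat("  params:", paste(names(x$model_params), unlist(x$model_params),
                         sep = "=", collapse = ", "), "\n")
  cat(sprintf("  noise sigma=%g um, drift=(%g, %g) um/s, seed=%d\n",
              x$localization_noise_sigma, x$drift_velocity[1],
              x$drift_velocity[2], x$seed))
  invisible(x)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Documented splitting scheme: master seed -> (dynamics, noise, placement).
split_seed <- function(seed, n = 3L) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
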