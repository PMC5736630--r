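KB <- 1.380649e-23  # Boltzmann constant, J/K

#' Stokes-Einstein thermal diffusivity
#'
#' `D = kB T / (6 pi eta R)`, the thermal reference against which measured
#' apparent diffusivities are compared to flag active (bacteria-driven)
#' transport.
#'
#' @param probe_radius Probe radius in metres (e.g. `0.5e-6` for the 0.5 um
#'   polystyrene probes).
#' @param viscosity Dynamic viscosity in Pa s (water at 25C: 0.89e-3).
#' @param temperature Temperature in K (default 298).
#' @return Diffusivity in um^2/s.
#' @export
thermal_diffusivity <- function(probe_radius, viscosity = 0.89e-3,
                                temperature = 298) {
  if (any(c(probe_radius, viscosity, temperature) <= 0))
    stop("probe_radius, viscosity and temperature must all be > 0")
  KB * temperature / (6 * pi * viscosity * probe_radius) * 1e12
}

#' Apparent diffusivity at a reference lag, and the activity ratio
#'
#' `D_app = MSD(lag) / (4 lag)` read off the measured curve at the grid lag
#' nearest `at_lag`. For genuinely diffusive motion this is lag-independent;
#' for arrested probes it decays as 1/lag. The activity ratio
#' `D_app / D_thermal` exceeds 1 when probe motion outruns thermal
#' diffusion, the signature of active driving.
#'
#' @param msd An `msd_curve`.
#' @param at_lag Lag time in seconds; must lie within the measured range.
#' @return `apparent_diffusivity()`: D_app in um^2/s.
#' @export
apparent_diffusivity <- function(msd, at_lag) {
  stopifnot(inherits(msd, "msd_curve"))
  rng <- range(msd$lag_s)
  if (at_lag < rng[1] * 0.99 || at_lag > rng[2] * 1.01)
    stop(sprintf("at_lag = %g s outside measured lags [%g, %g] s",
                 at_lag, rng[1], rng[2]))
  i <- which.min(abs(msd$lag_s - at_lag))
  msd$msd_um2[i] / (4 * msd$lag_s[i])
}

#' @rdname apparent_diffusivity
#' @param d_app,d_thermal Diffusivities in the same units.
#' @param active_margin Flag `active = TRUE` when the ratio exceeds this.
#' @return `activity_ratio()`: list with `ratio` and logical `active`.
#' @export
activity_ratio <- function(d_app, d_thermal, active_margin = 1.5) {
  stopifnot(d_thermal > 0)
  r <- d_app / d_thermal
  list(ratio = r, active = r > active_margin)
}

#' Interfacial trapping energy
#'
#' Free-energy gain `E = gamma * delta_area` when an adsorbed particle or
#' cell eliminates a patch of fluid-fluid interface; expressed both in
#' joules and in units of kB T. For micrometre-scale objects at an
#' oil-water interface this is of order 10^7 kB T, which is why adsorption
#' is effectively irreversible.
#'
#' @param gamma Interfacial tension in N/m.
#' @param delta_area Interfacial area removed, m^2.
#' @param temperature Temperature in K for the kB T conversion.
#' @return List with `energy_J` and `energy_kT`.
#' @export
trapping_energy <- function(gamma, delta_area, temperature = 298) {
  if (gamma < 0 || delta_area < 0)
    stop("gamma and delta_area must be >= 0")
  e <- gamma * delta_area
  list(energy_J = e, energy_kT = e / (KB * temperature))
}
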