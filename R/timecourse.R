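#' Analyze one interface age: drift correction, MSD, fit, classification
#'
#' The per-age analysis chain applied to one trajectory ensemble:
#' [subtract_drift()] (unless disabled), [ensemble_msd()],
#' [fit_power_law()], [classify_regime()], plus the apparent diffusivity at
#' the reference lag.
#'
#' @param ensemble A [traj_ensemble()].
#' @param window,ref_lag Passed to [fit_power_law()].
#' @param elastic_max,diffusive_band Passed to [classify_regime()].
#' @param max_lag_frames,min_traj_length Passed to [ensemble_msd()].
#' @param drift_correction Apply ensemble drift correction first (default
#'   `TRUE`, the standard order; disable only for diagnostics).
#' @return An `age_summary` list: `surface_age`, `fit` (power_law_fit),
#'   `label` (regime_label), `n_traj`, `d_app`, `msd` (the msd_curve).
#' @export
analyze_age <- function(ensemble, window = c(1.67e-2, 1.67), ref_lag = 1.67,
                        elastic_max = 0.1, diffusive_band = c(0.9, 1.1),
                        max_lag_frames = 100L, min_traj_length = 110L,
                        drift_correction = TRUE) {
  if (drift_correction) ensemble <- subtract_drift(ensemble)
  msd <- ensemble_msd(ensemble, max_lag_frames = max_lag_frames,
                      min_traj_length = min_traj_length)
  fit <- fit_power_law(msd, window = window, ref_lag = ref_lag)
  label <- classify_regime(fit, elastic_max = elastic_max,
                           diffusive_band = diffusive_band)
  structure(list(surface_age = attr(ensemble, "surface_age"),
                 fit = fit, label = label,
                 n_traj = n_trajectories(ensemble),
                 d_app = apparent_diffusivity(msd, fit$d_lag_s),
                 msd = msd),
            class = "age_summary")
}

#' Interface-age time course with transition detection
#'
#' Runs the per-age analysis over an ordered series of trajectory ensembles
#' (one per surface age) and locates the two film-formation milestones:
#' `subdiffusive_onset_age`, the first age whose exponent falls below the
#' diffusive band, and `transition_age`, the first age classified elastic
#' (n below the elastic threshold). Either is `NA` when never reached.
#' Detection is first-crossing of the label sequence, with no smoothing.
#'
#' @param ensembles List of [traj_ensemble()] objects, each carrying a
#'   `surface_age` attribute; ages must be strictly increasing.
#' @param min_traj_count Ages with fewer trajectories are skipped with a
#'   warning and recorded in `skipped_ages`.
#' @param ... Passed to [analyze_age()].
#' @return A `timecourse_result`: `summary` (data.frame with columns
#'   `age_s`, `n`, `d_um`, `regime`, `D_app`, `n_traj`), `transition_age`,
#'   `subdiffusive_onset_age`, `skipped_ages`, and `ages` (the per-age
#'   `age_summary` objects).
#' @export
analyze_timecourse <- function(ensembles, min_traj_count = 10L, ...) {
  stopifnot(length(ensembles) >= 2L)
  ages <- vapply(ensembles, function(e) as.numeric(attr(e, "surface_age")),
                 numeric(1))
  if (any(!is.finite(ages)) || any(diff(ages) <= 0))
    stop("ensembles must carry strictly increasing surface_age attributes")
  keep <- vapply(ensembles, n_trajectories, integer(1)) >= min_traj_count
  if (any(!keep))
    warning("skipping ", sum(!keep), " age(s) with fewer than ",
            min_traj_count, " trajectories: ",
            paste(ages[!keep], collapse = ", "))
  summaries <- lapply(ensembles[keep], analyze_age, ...)
  sm <- data.frame(
    age_s = ages[keep],
    n = vapply(summaries, function(s) s$fit$exponent, numeric(1)),
    d_um = vapply(summaries, function(s) s$fit$d_um, numeric(1)),
    regime = vapply(summaries, function(s) s$label$regime, character(1)),
    D_app = vapply(summaries, function(s) s$d_app, numeric(1)),
    n_traj = vapply(summaries, function(s) s$n_traj, integer(1)))
  band_lo <- summaries[[1]]$label$thresholds$diffusive_band[1]
  onset <- sm$age_s[sm$n < band_lo]
  trans <- sm$age_s[sm$regime == "elastic"]
  structure(list(summary = sm,
                 transition_age = if (length(trans)) trans[1] else NA_real_,
                 subdiffusive_onset_age =
                   if (length(onset)) onset[1] else NA_real_,
                 skipped_ages = ages[!keep],
                 ages = summaries),
            class = "timecourse_result")
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat("<timecourse_result>\n")
  print(x$summary, digits = 3)
  cat(sprintf("subdiffusive onset: %s s;  elastic transition: %s s\n",
              format(x$subdiffusive_onset_age),
              format(x$transition_age)))
  invisible(x)
}

#' @export
plot.timecourse_result <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$summary$age_s, x$summary$n, log = "x", pch = 16,
                 xlab = "surface age (s)", ylab = "exponent n",
                 ylim = c(0, max(2, x$summary$n)), ...)
  graphics::abline(h = c(0.1, 1), lty = c(3, 2))
  graphics::par(new = TRUE)
  graphics::plot(x$summary$age_s, x$summary$d_um, log = "xy", pch = 1,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext(expression(d(1.67 * s) ~ (mu * m)), side = 4, line = 2.5)
}
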