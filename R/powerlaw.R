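#' Fit a power law to an MSD curve over a lag window
#'
#' Unweighted least-squares regression of `log10(MSD)` on `log10(lag)`
#' restricted to the window, giving `MSD ~ prefactor * t^n`. The default
#' window, 1.67e-2 to 1.67 s, spans lag 1 to lag 100 at 60 fps (window
#' endpoints are matched with 1% relative slack so the rounded printed
#' values capture the exact grid lags 1/60 and 100/60 s). The mobility
#' magnitude `d` is the square root of the measured MSD at the grid lag
#' nearest the reference lag (1.67 s) inside the window — a property of the
#' data, not of the fitted line.
#'
#' @param msd An `msd_curve` from [ensemble_msd()] or [trajectory_msd()].
#' @param window Length-2 numeric, lag window in seconds.
#' @param ref_lag Reference lag (s) at which `d = sqrt(MSD)` is reported.
#' @return A `power_law_fit` list: `exponent` (n), `prefactor` (um^2/s^n),
#'   `d_um`, `d_lag_s` (the grid lag actually used), `window`, `r_squared`,
#'   `n_points`, `n_zero_dropped`.
#' @export
fit_power_law <- function(msd, window = c(1.67e-2, 1.67), ref_lag = 1.67) {
  stopifnot(inherits(msd, "msd_curve"), length(window) == 2L,
            window[1] < window[2])
  slack <- 0.01
  inw <- msd$lag_s >= window[1] * (1 - slack) &
         msd$lag_s <= window[2] * (1 + slack) &
         is.finite(msd$msd_um2)
  zero <- inw & msd$msd_um2 <= 0
  n_zero <- sum(zero)
  if (n_zero)
    message(n_zero, " zero-valued MSD point(s) excluded from the log-log fit")
  use <- inw & msd$msd_um2 > 0
  if (sum(use) < 3L)
    stop("need at least 3 positive MSD points inside the window [",
         window[1], ", ", window[2], "] s; have ", sum(use))
  lx <- log10(msd$lag_s[use]); ly <- log10(msd$msd_um2[use])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)

  ref_idx <- which(inw)[which.min(abs(msd$lag_s[inw] - ref_lag))]
  d_lag <- msd$lag_s[ref_idx]
  d <- sqrt(max(msd$msd_um2[ref_idx], 0))

  structure(list(exponent = unname(fit$coefficients[2]),
                 prefactor = 10^unname(fit$coefficients[1]),
                 d_um = d, d_lag_s = d_lag,
                 window = window, r_squared = r2,
                 n_points = sum(use), n_zero_dropped = n_zero),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> n = %.3f, prefactor = %.4g um^2/s^n\n",
              x$exponent, x$prefactor))
  cat(sprintf("  d(%.3g s) = %.3g um; window [%g, %g] s; R^2 = %.4f (%d pts)\n",
              x$d_lag_s, x$d_um, x$window[1], x$window[2], x$r_squared,
              x$n_points))
  invisible(x)
}

#' Classify the viscoelastic regime from a fitted MSD exponent
#'
#' Maps the exponent n onto the four regimes used to stage interfacial film
#' formation: `n < elastic_max` (default 0.1) is an essentially solid
#' elastic film; exponents below the diffusive band are subdiffusive
#' (viscoelastic); within the band, diffusive; above it, superdiffusive
#' (active transport). The thresholds partition the n axis and are echoed
#' in the returned label.
#'
#' @param fit A `power_law_fit`, or a bare numeric exponent.
#' @param elastic_max Upper exponent bound for the elastic label.
#' @param diffusive_band Length-2 numeric band of exponents labelled
#'   diffusive.
#' @return A `regime_label`: list with `regime` (character), `exponent`,
#'   and `thresholds`.
#' @export
classify_regime <- function(fit, elastic_max = 0.1,
                            diffusive_band = c(0.9, 1.1)) {
  n <- if (inherits(fit, "power_law_fit")) fit$exponent else as.numeric(fit)
  stopifnot(is.finite(n), elastic_max <= diffusive_band[1],
            diffusive_band[1] < diffusive_band[2])
  regime <-
    if (n < elastic_max) "elastic"
    else if (n < diffusive_band[1]) "subdiffusive"
    else if (n <= diffusive_band[2]) "diffusive"
    else "superdiffusive"
  structure(list(regime = regime, exponent = n,
                 thresholds = list(elastic_max = elastic_max,
                                   diffusive_band = diffusive_band)),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s (n = %.3f; elastic < %g, diffusive [%g, %g])\n",
              x$regime, x$exponent, x$thresholds$elastic_max,
              x$thresholds$diffusive_band[1], x$thresholds$diffusive_band[2]))
  invisible(x)
}
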