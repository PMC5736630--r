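one_traj <- function(x, y, fps = 1) {
  traj_ensemble(data.frame(particle = 1L, frame = seq_along(x) - 1L,
                           x = x, y = y), fps = fps)
}

test_that("trajectory MSD matches hand-computed and closed-form values", {
  # positions (0,0), (1,0), (1,1) at 1 fps
  tr <- one_traj(c(0, 1, 1), c(0, 0, 1))
  m <- trajectory_msd(as.data.frame(tr), fps = 1, max_lag_frames = 2)
  expect_equal(m$msd_um2, c((1 + 1) / 2, 2))
  expect_equal(m$lag_s, c(1, 2))

  # constant trajectory
  m0 <- trajectory_msd(data.frame(frame = 0:9, x = 3, y = -2), fps = 60,
                       max_lag_frames = 5)
  expect_equal(m0$msd_um2, rep(0, 5))

  # ballistic: MSD(k) = (v k / fps)^2 exactly
  v <- 0.7; fps <- 60
  tr2 <- data.frame(frame = 0:49, x = v * (0:49) / fps, y = 0)
  m2 <- trajectory_msd(tr2, fps = fps, max_lag_frames = 10)
  expect_equal(m2$msd_um2, (v * (1:10) / fps)^2, tolerance = 1e-12)

  expect_error(trajectory_msd(data.frame(frame = 0, x = 1, y = 1), 60),
               "at least 2")
  expect_message(trajectory_msd(tr2, fps, max_lag_frames = 500),
                 "truncated")
})

test_that("ensemble MSD is the unweighted mean of per-trajectory MSDs", {
  # two trajectories engineered to MSD(1) = 1.0 and 3.0 um^2
  a <- data.frame(particle = 1L, frame = 0:2, x = c(0, 1, 2), y = 0)
  b <- data.frame(particle = 2L, frame = 0:2, x = 0,
                  y = sqrt(3) * c(0, 1, 2))
  ens <- traj_ensemble(rbind(a, b), fps = 1)
  m <- ensemble_msd(ens, max_lag_frames = 1, min_traj_length = 3)
  expect_equal(m$msd_um2, 2.0)
  expect_equal(m$n_traj, 2L)

  # ensemble of identical trajectories equals the individual MSD
  cc <- transform(a, particle = 3L)
  ens2 <- traj_ensemble(rbind(a, cc), fps = 1)
  m1 <- trajectory_msd(a, fps = 1, max_lag_frames = 2)
  m2 <- ensemble_msd(ens2, max_lag_frames = 2, min_traj_length = 3)
  expect_equal(m2$msd_um2, m1$msd_um2)

  expect_error(ensemble_msd(ens, min_traj_length = 100), "min_traj_length")
})

test_that("power-law fit is exact on noiseless power-law inputs", {
  lags <- (1:100) / 60
  # 4 D t with D = 0.15: n = 1, prefactor 0.6, d = sqrt(4 * 0.15 * 100/60)
  m <- ptmr:::msd_curve(lags, 4 * 0.15 * lags, rep(200L, 100), 60)
  f <- fit_power_law(m)
  expect_equal(f$exponent, 1, tolerance = 1e-10)
  expect_equal(f$prefactor, 0.6, tolerance = 1e-10)
  expect_equal(f$d_um, sqrt(4 * 0.15 * 100 / 60), tolerance = 1e-12)
  expect_equal(f$d_lag_s, 100 / 60)

  for (n_true in c(0, 0.4, 1.3, 2)) {
    mm <- ptmr:::msd_curve(lags, 0.5 * lags^n_true, rep(10L, 100), 60)
    expect_equal(fit_power_law(mm)$exponent, n_true, tolerance = 1e-9)
  }
  # flat MSD: n = 0, d = 0.1 um
  fl <- fit_power_law(ptmr:::msd_curve(lags, rep(0.010, 100),
                                       rep(10L, 100), 60))
  expect_equal(fl$exponent, 0, tolerance = 1e-12)
  expect_equal(fl$d_um, 0.1, tolerance = 1e-12)
})

test_that("power-law fit drops zero MSD values and demands 3 usable points", {
  lags <- (1:10) / 6
  vals <- 0.5 * lags; vals[2] <- 0
  m <- ptmr:::msd_curve(lags, vals, rep(5L, 10), 6)
  expect_message(f <- fit_power_law(m, window = c(0.1, 2)), "excluded")
  expect_equal(f$exponent, 1, tolerance = 1e-9)
  sparse <- ptmr:::msd_curve(lags, c(0.1, 0.2, rep(0, 8)), rep(5L, 10), 6)
  expect_error(fit_power_law(sparse, window = c(0.1, 2)), "at least 3")
})

test_that("regime classification partitions the exponent axis at the stated
           thresholds", {
  lab <- classify_regime(0.05)
  expect_equal(lab$regime, "elastic")
  expect_equal(lab$thresholds$elastic_max, 0.1)
  expect_equal(classify_regime(0.09)$regime, "elastic")
  expect_equal(classify_regime(0.11)$regime, "subdiffusive")
  expect_equal(classify_regime(0.5)$regime, "subdiffusive")
  expect_equal(classify_regime(1.0)$regime, "diffusive")
  expect_equal(classify_regime(1.4)$regime, "superdiffusive")
  # threshold monotonicity: increasing n never moves the label toward elastic
  order_ <- c(elastic = 1, subdiffusive = 2, diffusive = 3,
              superdiffusive = 4)
  grid <- seq(-0.2, 2.2, by = 0.01)
  ranks <- order_[vapply(grid, function(n) classify_regime(n)$regime,
                         character(1))]
  expect_true(all(diff(ranks) >= 0))
})

test_that("drift correction removes common-mode motion to machine precision
           and warns on a single trajectory", {
  cfg <- sim_config("arrested", 8, 60,
                    model_params = list(sigma_eq = 0, tau_r = 1e-3),
                    seed = 2)
  gt <- simulate_trajectories(cfg)
  dr <- cbind(cumsum(runif(60, -1, 1)), cumsum(runif(60, -1, 1)))
  dr <- dr - rep(dr[1, ], each = 60)
  corr <- subtract_drift(apply_drift(gt, dr))
  steps <- unlist(tapply(corr$x, corr$particle, diff))
  expect_lt(max(abs(steps)), 1e-10)

  single <- traj_ensemble(data.frame(particle = 1L, frame = 0:9,
                                     x = cumsum(rnorm(10)), y = 0), fps = 60)
  expect_warning(s <- subtract_drift(single), "single")
  expect_lt(max(abs(diff(s$x))), 1e-12)
})

test_that("drift-corrected Brownian motion recovers D through the (N-1)/N
           finite-ensemble factor", {
  N <- 100
  cfg <- sim_config("brownian", N, 600, model_params = list(D = 0.15),
                    seed = 71)
  gt <- simulate_trajectories(cfg)
  m_raw <- ensemble_msd(gt, max_lag_frames = 50, min_traj_length = 500)
  m_cor <- ensemble_msd(subtract_drift(gt), max_lag_frames = 50,
                        min_traj_length = 500)
  ratio <- m_cor$msd_um2 / m_raw$msd_um2
  expect_equal(mean(ratio), (N - 1) / N, tolerance = 0.01)

  # paired-seed oracle: adding drift then correcting reproduces the
  # drift-free analysis to within 5% on the fitted diffusivity
  drifted <- apply_drift(gt, cbind(0.5 * (0:599), 0.25 * (0:599)))
  f_ref <- fit_power_law(m_cor)
  f_dr <- fit_power_law(ensemble_msd(subtract_drift(drifted),
                                     max_lag_frames = 50,
                                     min_traj_length = 500))
  expect_equal(f_dr$prefactor, f_ref$prefactor, tolerance = 1e-10)
  expect_equal(f_dr$prefactor / 4, 0.15, tolerance = 0.05)
})

test_that("apparent diffusivity reads 4Dt curves back as D and flags
           arrest by its 1/lag decay", {
  lags <- (1:100) / 60
  m <- ptmr:::msd_curve(lags, 4 * 0.15 * lags, rep(50L, 100), 60)
  for (lag in c(0.05, 0.5, 1.6))
    expect_equal(apparent_diffusivity(m, lag), 0.15, tolerance = 1e-12)
  expect_error(apparent_diffusivity(m, 5), "outside")

  flat <- ptmr:::msd_curve(lags, rep(0.01, 100), rep(50L, 100), 60)
  d_early <- apparent_diffusivity(flat, 0.1)
  d_late <- apparent_diffusivity(flat, 1.5)
  expect_gt(d_early, d_late)

  ar <- activity_ratio(0.98, 0.49)
  expect_equal(ar$ratio, 2.0)
  expect_true(ar$active)
  expect_false(activity_ratio(0.5, 0.49)$active)
})

test_that("Stokes-Einstein reference diffusivity and its scalings", {
  D <- thermal_diffusivity(0.5e-6, 0.89e-3, 298)
  expect_equal(D, 1.380649e-23 * 298 / (6 * pi * 0.89e-3 * 0.5e-6) * 1e12,
               tolerance = 1e-12)
  expect_equal(D, 0.49, tolerance = 0.01)
  expect_equal(thermal_diffusivity(1e-6, 0.89e-3, 298), D / 2)
  expect_equal(thermal_diffusivity(0.5e-6, 1.78e-3, 298), D / 2)
  expect_error(thermal_diffusivity(-1, 1, 1), "> 0")
})

test_that("interfacial trapping energy is gamma * area, reported in J and
           kB T", {
  expect_equal(trapping_energy(0.053, 0)$energy_J, 0)
  e <- trapping_energy(0.053, pi * (0.5e-6)^2, temperature = 298)
  expect_equal(e$energy_J, 0.053 * pi * 0.25e-12, tolerance = 1e-12)
  expect_equal(e$energy_J, 4.2e-14, tolerance = 0.01)
  expect_equal(e$energy_kT, e$energy_J / (1.380649e-23 * 298))
  expect_equal(e$energy_kT, 1.0e7, tolerance = 0.02)
  expect_equal(trapping_energy(2 * 0.053, pi * 0.25e-12)$energy_J,
               2 * e$energy_J)
})
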