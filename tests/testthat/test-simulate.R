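test_that("identical config and seed reproduce trajectories byte-for-byte", {
  cfg <- sim_config("brownian", 10, 50, model_params = list(D = 0.2),
                    seed = 99)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectories(a, f1); write_trajectories(b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  cfg2 <- sim_config("brownian", 10, 50, model_params = list(D = 0.2),
                     seed = 100)
  expect_false(identical(as.data.frame(simulate_trajectories(cfg2)),
                         as.data.frame(a)))
})

test_that("seed splitting isolates noise from dynamics", {
  base <- function(noise) sim_config("brownian", 5, 40,
                                     localization_noise_sigma = noise,
                                     model_params = list(D = 0.1), seed = 7)
  clean <- simulate_trajectories(base(0))
  noisy <- simulate_trajectories(base(0.05))
  # the underlying dynamics realization is unchanged by switching noise on
  expect_false(identical(clean$x, noisy$x))
  expect_lt(max(abs(clean$x - noisy$x)), 0.05 * 6)
})

test_that("zero diffusivity gives constant positions and zero MSD", {
  cfg <- sim_config("brownian", 4, 30, model_params = list(D = 0),
                    seed = 3)
  gt <- simulate_trajectories(cfg)
  expect_equal(tapply(gt$x, gt$particle, function(v) max(abs(diff(v)))),
               tapply(gt$x, gt$particle, function(v) 0))
  m <- ensemble_msd(gt, max_lag_frames = 10, min_traj_length = 20)
  expect_equal(m$msd_um2, rep(0, 10))
})

test_that("Brownian ensemble MSD matches 4Dt within 3 SE at every lag", {
  cfg <- sim_config("brownian", 200, 500, model_params = list(D = 0.15),
                    seed = 41)
  gt <- simulate_trajectories(cfg)
  o <- ensemble_msd_se(gt, 50)
  expect_true(all(abs(o$mean - 4 * 0.15 * (1:50) / 60) <= 3 * o$se))
})

test_that("fBm generator covariance matches the analytic form and the
           Cholesky oracle on a 32-step grid", {
  H <- 0.3; scale <- 0.7; dt <- 1 / 60; n <- 32
  # Cholesky oracle reproduces the analytic fBm covariance exactly
  L <- ptmr:::fgn_chol_factor(n, H, scale, dt)
  A <- matrix(0, n, n); A[lower.tri(A, diag = TRUE)] <- 1
  expect_equal(A %*% (L %*% t(L)) %*% t(A),
               fbm_covariance((1:n) * dt, H, scale), tolerance = 1e-12)
  # circulant-embedding sampler agrees with the analytic covariance
  lam <- ptmr:::fgn_dh_eigenvalues(n, H, scale, dt)
  expect_false(is.null(lam))
  set.seed(7)
  X <- t(replicate(20000, ptmr:::fgn_sample_dh(lam, n)))
  B <- t(apply(X, 1, cumsum))
  Cemp <- crossprod(B) / nrow(B)
  Cana <- fbm_covariance((1:n) * dt, H, scale)
  expect_lt(max(abs(Cemp - Cana)) / max(Cana), 0.03)
})

test_that("fBm with H = 1/2 has uncorrelated increments", {
  cfg <- sim_config("fbm", 100, 400, model_params = list(H = 0.5, scale = 1),
                    seed = 13)
  gt <- simulate_trajectories(cfg)
  ac <- sapply(split(gt$x, gt$particle), function(v) {
    d <- diff(v); stats::cor(d[-1], d[-length(d)])
  })
  expect_lt(abs(mean(ac)), 3 / sqrt(length(ac) * 400))
})

test_that("fBm exponent recovery: fitted n equals 2H", {
  for (H in c(0.3, 0.7)) {
    cfg <- sim_config("fbm", 150, 600,
                      model_params = list(H = H, scale = 0.2),
                      seed = 1000 + round(100 * H))
    m <- ensemble_msd(simulate_trajectories(cfg))
    expect_equal(fit_power_law(m)$exponent, 2 * H, tolerance = 0.05)
  }
})

test_that("persistent random walk matches its closed-form MSD within 3 SE", {
  v <- 2; tau <- 0.5
  cfg <- sim_config("prw", 300, 400, model_params = list(v = v, tau_p = tau),
                    seed = 31)
  gt <- simulate_trajectories(cfg)
  o <- ensemble_msd_se(gt, 100)
  t <- (1:100) / 60
  th <- 2 * v^2 * tau^2 * (t / tau - 1 + exp(-t / tau))
  expect_true(all(abs(o$mean - th) <= 3 * o$se))
})

test_that("PRW limits: ballistic when tau_p >> duration, diffusive when
           tau_p << frame interval", {
  bal <- sim_config("prw", 150, 300, model_params = list(v = 1, tau_p = 100),
                    seed = 8)
  m <- ensemble_msd(simulate_trajectories(bal), max_lag_frames = 100,
                    min_traj_length = 150)
  expect_equal(fit_power_law(m)$exponent, 2, tolerance = 0.05)
  # tau_p = 1e-3 s << 1/60 s; v^2 tau_p = 2 fixes the effective diffusivity
  dif <- sim_config("prw", 200, 500,
                    model_params = list(v = sqrt(2 / 1e-3), tau_p = 1e-3),
                    seed = 9)
  m2 <- ensemble_msd(simulate_trajectories(dif))
  expect_equal(fit_power_law(m2)$exponent, 1, tolerance = 0.05)
})

test_that("arrested probes: zero amplitude is exactly static; localization
           noise alone gives the flat 4 sigma^2 noise floor", {
  silent <- sim_config("arrested", 5, 50,
                       model_params = list(sigma_eq = 0, tau_r = 1e-3),
                       seed = 4)
  m0 <- ensemble_msd(simulate_trajectories(silent), max_lag_frames = 20,
                     min_traj_length = 40)
  expect_equal(m0$msd_um2, rep(0, 20))

  noisy <- sim_config("arrested", 100, 500, localization_noise_sigma = 0.05,
                      model_params = list(sigma_eq = 0, tau_r = 1e-3),
                      seed = 5)
  gt <- simulate_trajectories(noisy)
  o <- ensemble_msd_se(gt, 50)
  expect_true(all(abs(o$mean - 4 * 0.05^2) <= 3 * o$se))
})

test_that("fast-relaxing tethered probes give a flat MSD of 4 sigma_eq^2", {
  cfg <- sim_config("arrested", 150, 400,
                    model_params = list(sigma_eq = 0.05, tau_r = 1e-3),
                    seed = 6)
  o <- ensemble_msd_se(simulate_trajectories(cfg), 50)
  expect_true(all(abs(o$mean - 4 * 0.05^2) <= 3 * o$se))
})

test_that("apply_drift shifts every particle identically and is exactly
           invertible", {
  cfg <- sim_config("arrested", 6, 40,
                    model_params = list(sigma_eq = 0, tau_r = 1e-3),
                    seed = 12)
  gt <- simulate_trajectories(cfg)
  nf <- 40
  expect_identical(apply_drift(gt, matrix(0, nf, 2)), gt)

  # constant 0.5 um/frame on static particles: exact per-frame displacement
  dr <- cbind(0.5 * (0:(nf - 1)), 0 * (0:(nf - 1)))
  shifted <- apply_drift(gt, dr)
  steps <- tapply(shifted$x, shifted$particle, diff)
  expect_true(all(vapply(steps, function(s) all(abs(s - 0.5) < 1e-12),
                         logical(1))))

  # sinusoidal drift: ensemble-mean frame-to-frame displacement equals the
  # drift increment exactly; removal restores the original positions
  dr2 <- cbind(sin((0:(nf - 1)) / 5), cos((0:(nf - 1)) / 7))
  wavy <- apply_drift(gt, dr2)
  mean_step_x <- as.numeric(tapply(wavy$x, wavy$frame, mean))
  expect_equal(diff(mean_step_x), diff(dr2[, 1]), tolerance = 1e-12)
  expect_equal(as.data.frame(remove_drift(wavy)), as.data.frame(gt),
               tolerance = 1e-12)
  expect_error(apply_drift(gt, matrix(0, nf - 1, 2)), "n_frames")
})

test_that("parameter validation rejects unphysical configurations", {
  expect_error(sim_config("brownian", 10, 50, model_params = list(D = -1)),
               "D")
  expect_error(sim_config("fbm", 10, 50,
                          model_params = list(H = 1.2, scale = 1)), "H")
  expect_error(sim_config("prw", 10, 50,
                          model_params = list(v = 1, tau_p = 0)), "tau_p")
  expect_error(sim_config("brownian", 0, 50, model_params = list(D = 1)),
               "n_particles")
  expect_error(sim_config("brownian", 10, 1, model_params = list(D = 1)),
               "n_frames")
})
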