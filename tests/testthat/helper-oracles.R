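# Shared oracles and fixture builders. Everything here is independent of the
# implementation paths it is used to check.

# Per-lag standard error of an ensemble MSD: sd over per-trajectory MSDs at
# that lag divided by sqrt(N). Used for "within 3 SE" closed-form checks.
ensemble_msd_se <- function(ensemble, max_lag, min_len = 2L) {
  parts <- split(as.data.frame(ensemble)[c("frame", "x", "y")],
                 ensemble$particle)
  parts <- Filter(function(p) nrow(p) >= min_len, parts)
  per <- sapply(parts, function(p) {
    sapply(seq_len(max_lag), function(k) {
      n <- nrow(p)
      if (k >= n) return(NA_real_)
      dx <- p$x[(k + 1):n] - p$x[1:(n - k)]
      dy <- p$y[(k + 1):n] - p$y[1:(n - k)]
      mean(dx^2 + dy^2)
    })
  })
  list(mean = rowMeans(per, na.rm = TRUE),
       se = apply(per, 1, stats::sd, na.rm = TRUE) /
         sqrt(rowSums(!is.na(per))))
}

# Brute-force linking oracle: minimum-cost one-to-one assignment between
# tracks (rows of p0) and candidates (rows of p1) where pairs farther than
# max_disp are forbidden and every unmatched track or candidate costs
# max_disp^2. Exhaustive over all assignments; tractable for <= 5 x 5.
brute_force_assignment <- function(p0, p1, max_disp) {
  nt <- nrow(p0); nc <- nrow(p1)
  d2 <- outer(seq_len(nt), seq_len(nc), function(i, j)
    (p0[i, 1] - p1[j, 1])^2 + (p0[i, 2] - p1[j, 2])^2)
  best <- list(cost = Inf, match = rep(NA_integer_, nc))
  recurse <- function(t, used, match, cost) {
    if (t > nt) {
      total <- cost + max_disp^2 * sum(is.na(match))
      if (total < best$cost) best <<- list(cost = total, match = match)
      return()
    }
    for (j in seq_len(nc)) {
      if (!used[j] && d2[t, j] <= max_disp^2) {
        used[j] <- TRUE; match[j] <- t
        recurse(t + 1L, used, match, cost + d2[t, j])
        used[j] <- FALSE; match[j] <- NA_integer_
      }
    }
    recurse(t + 1L, used, match, cost + max_disp^2)
  }
  recurse(1L, rep(FALSE, nc), rep(NA_integer_, nc), 0)
  best
}

# Render one SNR-10 frame of isolated spots on a jittered grid; returns the
# truth table (0-based px coordinates) and the image.
snr10_grid_frame <- function(n_spots = 50, nr = 288, peak = 8000,
                             noise = 800, psf_sigma = 1.5, seed = 1) {
  set.seed(seed)
  k <- ceiling(sqrt(n_spots))
  site <- seq(24, nr - 24, length.out = k)
  g <- expand.grid(x = site, y = site)[seq_len(n_spots), ]
  truth <- data.frame(x = g$x + runif(n_spots, -2, 2),
                      y = g$y + runif(n_spots, -2, 2))
  img <- matrix(1000, nr, nr)
  for (i in seq_len(n_spots)) {
    cols <- pmax(1, floor(truth$x[i]) - 7):pmin(nr, ceiling(truth$x[i]) + 7)
    rows <- pmax(1, floor(truth$y[i]) - 7):pmin(nr, ceiling(truth$y[i]) + 7)
    img[rows, cols] <- img[rows, cols] + peak *
      outer(exp(-((rows - 1) - truth$y[i])^2 / (2 * psf_sigma^2)),
            exp(-((cols - 1) - truth$x[i])^2 / (2 * psf_sigma^2)))
  }
  img <- img + matrix(rnorm(nr * nr, sd = noise), nr, nr)
  list(truth = truth, img = img)
}

# Single noiseless Gaussian spot image; position in 0-based px (x = col).
gaussian_spot <- function(px, py, nr = 64, nc = 64, sigma = 1.5,
                          peak = 8000, background = 0, aspect = 1) {
  cols <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  rows <- matrix(rep(0:(nr - 1), nc), nr, nc)
  background + peak * exp(-((cols - px)^2 / (2 * (sigma * aspect)^2) +
                            (rows - py)^2 / (2 * sigma^2)))
}

# Fixtures are expensive (two rendered movies); build them once per test run.
fixture_cache <- local({
  env <- new.env()
  function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(env[[key]])) {
      dir <- file.path(tempdir(), paste0("ptmr_fixtures_", seed))
      fx <- make_fixtures(dir, seed = seed)
      env[[key]] <- list(dir = dir, fx = fx)
    }
    env[[key]]
  }
})
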