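#' Analytic fractional Brownian motion covariance
#'
#' Covariance of fBm positions, `Cov(x(s), x(t)) = scale/2 *
#' (s^(2H) + t^(2H) - |t - s|^(2H))`, evaluated on a grid of times.
#'
#' @param times Numeric vector of times (s), non-negative.
#' @param H Hurst exponent in (0, 1).
#' @param scale Variance coefficient (um^2 / s^(2H)).
#' @return `length(times)` square covariance matrix.
#' @export
fbm_covariance <- function(times, H, scale = 1) {
  stopifnot(H > 0, H < 1, all(times >= 0))
  s <- matrix(times, length(times), length(times))
  t <- t(s)
  scale / 2 * (s^(2 * H) + t^(2 * H) - abs(t - s)^(2 * H))
}

# Autocovariance of fractional Gaussian noise (unit-step increments of fBm
# sampled every dt): gamma(k) = scale * dt^(2H)/2 *
# (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)).
fgn_acov <- function(k, H, scale, dt) {
  scale * dt^(2 * H) / 2 *
    (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Circulant-embedding (Davies-Harte) eigenvalues for fGn of length n.
# Returns NULL when the embedding is not nonnegative definite (then the
# caller falls back to Cholesky).
fgn_dh_eigenvalues <- function(n, H, scale, dt) {
  g <- fgn_acov(0:n, H, scale, dt)
  circ <- c(g, g[n:2])                     # length 2n first row
  lam <- Re(stats::fft(circ))
  if (any(lam < -1e-8 * max(abs(lam)))) return(NULL)
  pmax(lam, 0)
}

# One fGn sample path of length n given precomputed embedding eigenvalues.
# Consumes exactly 2n normal deviates from the current RNG stream.
fgn_sample_dh <- function(lam, n) {
  m <- 2L * n
  z <- stats::rnorm(m)
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1] / m) * z[1]
  w[n + 1] <- sqrt(lam[n + 1] / m) * z[2]
  j <- seq_len(n - 1L)
  zj <- z[2L + j]
  zj2 <- z[2L + (n - 1L) + j]
  w[1L + j] <- sqrt(lam[1L + j] / (2 * m)) * complex(real = zj,
                                                     imaginary = zj2)
  w[m + 1L - j] <- Conj(w[1L + j])
  Re(stats::fft(w))[seq_len(n)]
}

# Lower Cholesky factor of the fGn covariance, the exact (O(n^3)) fallback
# and the independent oracle used in tests.
fgn_chol_factor <- function(n, H, scale, dt) {
  t(chol(stats::toeplitz(fgn_acov(0:(n - 1L), H, scale, dt))))
}

# n_paths fGn sample paths (rows) of length n. Method "dh" unless the
# embedding fails, then "chol".
fgn_sample <- function(n_paths, n, H, scale, dt, method = c("auto", "dh", "chol")) {
  method <- match.arg(method)
  lam <- if (method %in% c("auto", "dh")) fgn_dh_eigenvalues(n, H, scale, dt)
  if (!is.null(lam)) {
    out <- matrix(0, n_paths, n)
    for (i in seq_len(n_paths)) out[i, ] <- fgn_sample_dh(lam, n)
    return(out)
  }
  if (method == "dh")
    stop("circulant embedding not nonnegative definite for this grid")
  L <- fgn_chol_factor(n, H, scale, dt)
  z <- matrix(stats::rnorm(n_paths * n), n, n_paths)
  t(L %*% z)
}
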