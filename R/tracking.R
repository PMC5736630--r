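#' Spatial bandpass filter for spot images
#'
#' The preprocessing step of Crocker-Grier localization: suppress pixel
#' noise with a Gaussian of scale `noise_length` and remove long-wavelength
#' background with a boxcar of width `feature_diameter`, then clip at zero.
#' A perfectly flat image maps to all zeros; a symmetric spot keeps its
#' argmax. Edges are handled by replicate padding, so flat fields stay flat
#' right up to the border.
#'
#' @param frame 2-D numeric intensity matrix (rows = y, columns = x).
#' @param noise_length Gaussian noise scale in px (default 1).
#' @param feature_diameter Boxcar width in px; must be odd and larger than
#'   `noise_length`, smaller than the image sides.
#' @return Filtered matrix of the same shape, >= 0.
#' @export
bandpass <- function(frame, noise_length = 1, feature_diameter = 7L) {
  stopifnot(is.matrix(frame), noise_length > 0,
            feature_diameter > noise_length)
  if (feature_diameter >= min(dim(frame)))
    stop("feature_diameter must be smaller than the image sides")
  if (feature_diameter %% 2 == 0) stop("feature_diameter must be odd")
  half <- ceiling(3 * noise_length)
  g <- stats::dnorm(-half:half, sd = noise_length)
  g <- g / sum(g)
  smoothed <- conv_sep(frame, g)
  box <- rep(1 / feature_diameter, feature_diameter)
  background <- conv_sep(frame, box)
  pmax(smoothed - background, 0)
}

# Separable 2-D convolution with an odd symmetric 1-D kernel, replicate
# padding at the edges.
conv_sep <- function(img, kern) {
  conv_rows <- function(m) {
    half <- (length(kern) - 1L) / 2L
    n <- nrow(m)
    padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                    m[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (k in seq_along(kern))
      out <- out + kern[k] * padded[(k - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

#' Localize bright features with subpixel precision
#'
#' Candidate detection plus iterated intensity-weighted centroid
#' refinement. Candidates are local intensity maxima above the given
#' percentile of the image, separated by at least `feature_diameter`
#' (dimmer candidates inside that radius of a brighter one are suppressed).
#' Each candidate is refined by recomputing the intensity-weighted centroid
#' within a circular mask of radius `feature_diameter / 2`, walking the
#' mask one pixel when the centroid falls more than half a pixel from its
#' centre, up to `max_iter` times (non-convergence keeps the last estimate
#' and is flagged). Mass, radius-of-gyration size, and eccentricity
#' `sqrt(4 m_xy^2 + (m_xx - m_yy)^2) / (m_xx + m_yy)` (second central
#' moments) are measured within the mask.
#'
#' Coordinates are 0-based pixel indices at pixel centres: `x` = column,
#' `y` = row.
#'
#' @param frame 2-D intensity matrix, typically already bandpassed.
#' @param feature_diameter Odd integer spot extent in px.
#' @param percentile_threshold Intensity percentile (0-100) below which
#'   pixels cannot seed a candidate (default 64).
#' @param max_iter Centroid refinement iteration cap.
#' @return data.frame with columns `x`, `y`, `mass`, `size`, `ecc`,
#'   `converged`; zero rows when nothing is found.
#' @export
locate_features <- function(frame, feature_diameter = 7L,
                            percentile_threshold = 64, max_iter = 10L) {
  stopifnot(is.matrix(frame))
  d <- as.integer(feature_diameter)
  if (d %% 2 == 0) stop("feature_diameter must be odd")
  w <- d %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  thr <- stats::quantile(frame, percentile_threshold / 100, names = FALSE)

  dil <- dilate_max(frame, w)
  cand <- which(frame >= dil & frame > thr & frame > 0, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), mass = numeric(0),
                      size = numeric(0), ecc = numeric(0),
                      converged = logical(0))
  if (nrow(cand) == 0L) return(empty)
  # brightest-first suppression at separation < feature_diameter
  ord <- order(frame[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1L):nrow(cand)
      dd <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][dd < d^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  # drop candidates whose mask would leave the image
  inb <- cand[, 1] > w & cand[, 1] <= nr - w &
         cand[, 2] > w & cand[, 2] <= nc - w
  cand <- cand[inb, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  off <- expand.grid(dr = -w:w, dc = -w:w)
  off <- off[off$dr^2 + off$dc^2 <= (d / 2)^2, ]
  res <- lapply(seq_len(nrow(cand)), function(i)
    refine_centroid(frame, cand[i, 1], cand[i, 2], off, w, max_iter))
  out <- do.call(rbind, res)
  out <- out[out$mass > 0, , drop = FALSE]
  # refinement can merge neighbouring candidates onto one spot
  if (nrow(out) > 1L) {
    dup <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(out) - 1L)) {
      if (dup[i]) next
      j <- (i + 1L):nrow(out)
      dd <- (out$x[j] - out$x[i])^2 + (out$y[j] - out$y[i])^2
      dup[j][dd < (d / 2)^2] <- TRUE
    }
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Grey dilation (running max) over a (2w+1)^2 neighbourhood.
dilate_max <- function(img, w) {
  shift_max <- function(m, by, dim) {
    n <- dim(m)[dim]
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    if (dim == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  }
  out <- img
  for (s in setdiff(-w:w, 0L)) out <- pmax(out, shift_max(img, s, 1L))
  res <- out
  for (s in setdiff(-w:w, 0L)) res <- pmax(res, shift_max(out, s, 2L))
  res
}

refine_centroid <- function(frame, r0, c0, off, w, max_iter) {
  nr <- nrow(frame); nc <- ncol(frame)
  r <- r0; c <- c0
  converged <- FALSE
  dr_off <- 0; dc_off <- 0
  for (it in seq_len(max_iter)) {
    rows <- r + off$dr; cols <- c + off$dc
    ok <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
    iv <- frame[cbind(rows[ok], cols[ok])]
    m0 <- sum(iv)
    if (m0 <= 0) return(data.frame(x = c - 1, y = r - 1, mass = 0, size = 0,
                                   ecc = 0, converged = FALSE))
    dr_off <- sum(iv * off$dr[ok]) / m0
    dc_off <- sum(iv * off$dc[ok]) / m0
    if (abs(dr_off) <= 0.5 && abs(dc_off) <= 0.5) { converged <- TRUE; break }
    r <- min(max(r + sign(round(dr_off)), 1L + w), nr - w)
    c <- min(max(c + sign(round(dc_off)), 1L + w), nc - w)
  }
  rows <- r + off$dr; cols <- c + off$dc
  ok <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
  iv <- frame[cbind(rows[ok], cols[ok])]
  m0 <- sum(iv)
  dy <- off$dr[ok] - dr_off
  dx <- off$dc[ok] - dc_off
  mxx <- sum(iv * dx * dx) / m0
  myy <- sum(iv * dy * dy) / m0
  mxy <- sum(iv * dx * dy) / m0
  ecc <- if (mxx + myy > 0)
    sqrt(4 * mxy^2 + (mxx - myy)^2) / (mxx + myy) else 0
  data.frame(x = (c - 1) + dc_off, y = (r - 1) + dr_off, mass = m0,
             size = sqrt(mxx + myy), ecc = ecc, converged = converged)
}

#' Threshold filtering of localized features
#'
#' Keeps a feature iff `mass >= min_mass`, `size` within `size_range`, and
#' `ecc <= max_ecc`. The number rejected by each criterion is attached as
#' attribute `rejected` (a named vector), so filter settings are auditable.
#'
#' @param features data.frame from [locate_features()].
#' @param min_mass Minimum integrated intensity.
#' @param size_range Length-2 numeric `[size_min, size_max]` in px.
#' @param max_ecc Maximum eccentricity in (0, 1].
#' @return The retained rows, with a `rejected` attribute.
#' @export
filter_features <- function(features, min_mass = 0,
                            size_range = c(0, Inf), max_ecc = 1) {
  stopifnot(size_range[1] < size_range[2], max_ecc > 0, max_ecc <= 1)
  bad_mass <- features$mass < min_mass
  bad_size <- features$size < size_range[1] | features$size > size_range[2]
  bad_ecc <- features$ecc > max_ecc
  keep <- !(bad_mass | bad_size | bad_ecc)
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- c(mass = sum(bad_mass), size = sum(bad_size),
                             ecc = sum(bad_ecc))
  out
}
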