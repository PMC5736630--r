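#' Image-stack container
#'
#' A `frame_stack` holds a grayscale video as a numeric 3-D array indexed
#' `(frame, row, column)` with intensities in native camera counts, plus
#' acquisition metadata.
#'
#' @param frames Numeric array `(n_frames, n_rows, n_cols)`, finite, >= 0.
#' @param fps Frames per second.
#' @param pixel_size Pixel size in um/px.
#' @param bit_depth Camera bit depth (default 16).
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps, pixel_size, bit_depth = 16L) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            all(is.finite(frames)), all(frames >= 0),
            fps > 0, pixel_size > 0)
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %g fps, %g um/px, %d-bit\n",
              d[1], d[2], d[3], x$fps, x$pixel_size, x$bit_depth))
  invisible(x)
}

#' Render ground-truth trajectories to a microscopy-like image stack
#'
#' Draws each particle in each frame as a 2-D Gaussian intensity spot on a
#' constant background with additive Gaussian pixel noise, converting
#' physical positions to pixels via `pixel_size`. `spot_aspect > 1`
#' elongates spots along the x axis (`sigma_x = psf_sigma * spot_aspect`),
#' which raises their measured eccentricity — useful for exercising shape
#' filters. Particles whose centres leave the field are clipped and
#' reported with a warning.
#'
#' Pixel convention: position (x, y) in px means x = column, y = row,
#' 0-based, at the centre of the pixel.
#'
#' @param truth A [traj_ensemble()] (positions in um).
#' @param image_shape `c(n_rows, n_cols)` in px.
#' @param pixel_size um per pixel.
#' @param psf_sigma Spot Gaussian sigma in px (> 0).
#' @param peak_intensity Peak counts of one spot above background.
#' @param background_level Constant background counts.
#' @param noise_sigma Additive Gaussian pixel noise sigma in counts.
#' @param spot_aspect Spot elongation ratio along x (default 1, circular).
#' @param noise_seed Seed for the pixel noise stream.
#' @return A [frame_stack()] carrying `fps` and `pixel_size`.
#' @export
render_video <- function(truth, image_shape = c(128L, 128L),
                         pixel_size = 0.1, psf_sigma = 1.5,
                         peak_intensity = 8000, background_level = 1000,
                         noise_sigma = 0, spot_aspect = 1,
                         noise_seed = 1L) {
  stopifnot(psf_sigma > 0, pixel_size > 0, spot_aspect >= 1)
  nr <- image_shape[1]; nc <- image_shape[2]
  frames_idx <- sort(unique(truth$frame))
  nf <- length(frames_idx)
  sx <- psf_sigma * spot_aspect
  sy <- psf_sigma
  hw_x <- ceiling(4 * sx); hw_y <- ceiling(4 * sy)
  stack <- array(background_level, dim = c(nf, nr, nc))
  clipped <- 0L
  for (fi in seq_len(nf)) {
    rows <- truth[truth$frame == frames_idx[fi], ]
    img <- stack[fi, , ]
    for (j in seq_len(nrow(rows))) {
      px <- rows$x[j] / pixel_size     # column
      py <- rows$y[j] / pixel_size     # row
      if (px < 0 || px > nc - 1 || py < 0 || py > nr - 1)
        clipped <- clipped + 1L
      c0 <- max(0L, floor(px) - hw_x); c1 <- min(nc - 1L, ceiling(px) + hw_x)
      r0 <- max(0L, floor(py) - hw_y); r1 <- min(nr - 1L, ceiling(py) + hw_y)
      if (c1 < c0 || r1 < r0) next
      cols <- c0:c1; rws <- r0:r1
      gx <- exp(-(cols - px)^2 / (2 * sx^2))
      gy <- exp(-(rws - py)^2 / (2 * sy^2))
      img[rws + 1L, cols + 1L] <- img[rws + 1L, cols + 1L] +
        peak_intensity * outer(gy, gx)
    }
    stack[fi, , ] <- img
  }
  if (clipped > 0L)
    warning(clipped, " particle position(s) outside the field were clipped")
  if (noise_sigma > 0)
    stack <- stack + with_seed(noise_seed,
      array(stats::rnorm(length(stack), sd = noise_sigma), dim = dim(stack)))
  maxval <- 2^16 - 1
  stack <- round(pmin(pmax(stack, 0), maxval))
  frame_stack(stack, fps = attr(truth, "fps"), pixel_size = pixel_size)
}

#' Write / read an image stack as multi-page 16-bit grayscale TIFF
#'
#' Metadata (fps, pixel size, bit depth) goes to a JSON sidecar
#' `<path>.meta.json`, since TIFF tags are not a reliable carrier for it.
#'
#' @param stack A [frame_stack()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  maxval <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(i) stack$frames[i, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(fps = stack$fps, pixel_size = stack$pixel_size,
                            bit_depth = stack$bit_depth),
                       sidecar_path_tif(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param fps,pixel_size Overrides when no sidecar exists.
#' @export
read_stack <- function(path, fps = NULL, pixel_size = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("corrupt or unreadable TIFF at ", path, ": ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  sc <- sidecar_path_tif(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  fps <- fps %||% meta$fps
  pixel_size <- pixel_size %||% meta$pixel_size
  if (is.null(fps) || is.null(pixel_size))
    stop("fps/pixel_size not given and no metadata sidecar found at ", sc)
  bit_depth <- meta$bit_depth %||% 16L
  maxval <- 2^bit_depth - 1
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- round(pages[[i]] * maxval)
  frame_stack(arr, fps = fps, pixel_size = pixel_size, bit_depth = bit_depth)
}

sidecar_path_tif <- function(path)
  paste0(sub("\\.tiff?$", "", path), ".meta.json")
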