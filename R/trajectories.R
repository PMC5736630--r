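#' Trajectory ensemble container
#'
#' A `traj_ensemble` is a data.frame with columns `particle` (integer id),
#' `frame` (0-based integer frame index), `x`, `y` (positions in
#' micrometres), plus acquisition metadata stored as attributes: `fps`
#' (frames per second), `pixel_size` (um/px, may be `NA` for ground truth
#' that never saw a camera) and optionally `surface_age` (s).
#'
#' @param df data.frame with columns `particle`, `frame`, `x`, `y`.
#' @param fps Frames per second (> 0).
#' @param pixel_size Pixel size in um/px, or `NA`.
#' @param surface_age Interface age in seconds, or `NA`.
#' @return The data.frame with class `traj_ensemble` and metadata attached.
#' @export
traj_ensemble <- function(df, fps, pixel_size = NA_real_,
                          surface_age = NA_real_) {
  need <- c("particle", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory table needs columns: ", paste(need, collapse = ", "))
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("trajectory positions must be finite")
  df <- df[order(df$particle, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  dup <- duplicated(df[c("particle", "frame")])
  if (any(dup)) stop("duplicate (particle, frame) rows in trajectory table")
  structure(df, fps = fps, pixel_size = pixel_size,
            surface_age = surface_age,
            class = c("traj_ensemble", "data.frame"))
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf("<traj_ensemble> %d trajectories, %d points, fps=%g",
              length(unique(x$particle)), nrow(x), attr(x, "fps")))
  if (!is.na(attr(x, "surface_age")))
    cat(sprintf(", surface age %g s", attr(x, "surface_age")))
  cat("\n")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

n_trajectories <- function(ensemble) length(unique(ensemble$particle))

# Subsetting a traj_ensemble keeps metadata.
keep_traj_meta <- function(new, old) {
  traj_ensemble(new, fps = attr(old, "fps"),
                pixel_size = attr(old, "pixel_size"),
                surface_age = attr(old, "surface_age"))
}

#' Write / read trajectory tables as CSV with a JSON metadata sidecar
#'
#' The CSV has columns `particle_id`, `frame`, `x_um`, `y_um`; the sidecar
#' (`<path>.meta.json`) records `fps`, `pixel_size`, `surface_age` and any
#' extra metadata supplied.
#'
#' @param ensemble A [traj_ensemble()].
#' @param path Output CSV path.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path, extra = list()) {
  out <- data.frame(particle_id = ensemble$particle,
                    frame = ensemble$frame,
                    x_um = ensemble$x, y_um = ensemble$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(fps = attr(ensemble, "fps"),
                 pixel_size = attr(ensemble, "pixel_size"),
                 surface_age = attr(ensemble, "surface_age")),
            extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_trajectories
#' @param fps,pixel_size,surface_age Overrides used when no sidecar exists.
#' @export
read_trajectories <- function(path, fps = NULL, pixel_size = NULL,
                              surface_age = NULL) {
  df <- utils::read.csv(path)
  need <- c("particle_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory CSV is missing columns: ", paste(miss, collapse = ", "))
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  fps <- fps %||% meta$fps
  if (is.null(fps))
    stop("fps not given and no metadata sidecar found at ", sc)
  traj_ensemble(data.frame(particle = df$particle_id, frame = df$frame,
                           x = df$x_um, y = df$y_um),
                fps = fps,
                pixel_size = pixel_size %||% meta$pixel_size %||% NA_real_,
                surface_age = surface_age %||% meta$surface_age %||% NA_real_)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")
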