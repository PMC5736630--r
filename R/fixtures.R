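#' Generate the packaged test fixtures
#'
#' Writes a small, fully deterministic fixture tree used by the tests and
#' examples: one Brownian movie (TIFF + ground truth), one arrested movie,
#' the two packaged aging scenarios as per-age trajectory CSVs with a
#' manifest, an expected-output JSON (computed here, at generation time),
#' and a checksum file covering everything.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Master seed (default 1).
#' @return Named list with `files` (relative paths), `checksums`, and
#'   `expected` (the expected-output list), invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rel <- character(0)
  add <- function(p) rel <<- c(rel, p)

  movie_cfg <- function(model, params)
    sim_config(model, n_particles = 40L, n_frames = 150L, fps = 60,
               box_size = 25.6, placement = "grid", seed = seed,
               model_params = params)
  movies <- list(
    brownian = movie_cfg("brownian", list(D = 0.15)),
    arrested = movie_cfg("arrested", list(sigma_eq = 0.05, tau_r = 1e-3)))
  expected <- list()
  for (nm in names(movies)) {
    gt <- simulate_trajectories(movies[[nm]])
    stack <- render_video(gt, image_shape = c(256L, 256L), pixel_size = 0.1,
                          psf_sigma = 1.5, peak_intensity = 8000,
                          background_level = 1000, noise_sigma = 800,
                          noise_seed = seed + 1L)
    write_stack(stack, file.path(out_dir, paste0(nm, "_movie.tif")))
    write_trajectories(gt, file.path(out_dir, paste0(nm, "_truth.csv")))
    add(paste0(nm, "_movie.tif")); add(paste0(nm, "_movie.meta.json"))
    add(paste0(nm, "_truth.csv")); add(paste0(nm, "_truth.meta.json"))
    fit <- fit_power_law(ensemble_msd(gt, max_lag_frames = 30L,
                                      min_traj_length = 120L),
                         window = c(1.67e-2, 0.5), ref_lag = 0.5)
    expected[[nm]] <- list(n = fit$exponent, d_um = fit$d_um,
                           regime = classify_regime(fit)$regime)
  }

  for (nm in c("PAO1_like", "PA14_like")) {
    scen <- build_aging_scenario(nm, seed = seed)
    sdir <- file.path(out_dir, nm)
    dir.create(sdir, showWarnings = FALSE)
    write_scenario(scen, file.path(sdir, "scenario.json"))
    add(file.path(nm, "scenario.json"))
    manifest <- list()
    for (s in scen$stanzas) {
      gt <- simulate_trajectories(s$config)
      attr(gt, "surface_age") <- s$age_s
      p <- sprintf("trajectories_age%08d.csv", as.integer(s$age_s))
      write_trajectories(gt, file.path(sdir, p))
      add(file.path(nm, p)); add(file.path(nm, sub("\\.csv$", ".meta.json", p)))
      manifest[[length(manifest) + 1L]] <-
        list(age_s = s$age_s, trajectory_file = p)
    }
    jsonlite::write_json(manifest, file.path(sdir, "ages.json"),
                         auto_unbox = TRUE, digits = NA)
    add(file.path(nm, "ages.json"))
  }

  jsonlite::write_json(expected, file.path(out_dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA)
  add("expected.json")
  sums <- tools::md5sum(file.path(out_dir, rel))
  names(sums) <- rel
  jsonlite::write_json(as.list(sums), file.path(out_dir, "checksums.json"),
                       auto_unbox = TRUE)
  invisible(list(files = rel, checksums = sums, expected = expected))
}

#' Validate the package's file formats at a path
#'
#' Checks that a file is readable as what its extension claims, that the
#' metadata sidecar is complete, and that a write-read round trip
#' preserves content. Returns a report rather than raising, so callers can
#' batch-validate a directory.
#'
#' @param path A `.tif` stack, trajectory `.csv`, or scenario `.json`.
#' @return A `format_report` list: `path`, `kind`, `ok`, `problems`
#'   (character vector, empty when clean).
#' @export
validate_formats <- function(path) {
  problems <- character(0)
  kind <- if (grepl("\\.tiff?$", path)) "tiff"
    else if (grepl("\\.csv$", path)) "trajectory_csv"
    else if (grepl("\\.json$", path)) "json"
    else "unknown"
  if (!file.exists(path)) {
    problems <- "file does not exist"
  } else if (kind == "tiff") {
    st <- tryCatch(read_stack(path), error = function(e) conditionMessage(e))
    if (is.character(st)) problems <- c(problems, st)
    else {
      sc <- jsonlite::read_json(sidecar_path_tif(path), simplifyVector = TRUE)
      for (key in c("fps", "pixel_size"))
        if (is.null(sc[[key]]))
          problems <- c(problems, paste0("sidecar missing key: ", key))
      tmp <- tempfile(fileext = ".tif")
      on.exit(unlink(c(tmp, sidecar_path_tif(tmp))), add = TRUE)
      write_stack(st, tmp)
      st2 <- read_stack(tmp)
      if (!isTRUE(all.equal(st$frames, st2$frames)))
        problems <- c(problems, "TIFF round trip altered pixel data")
    }
  } else if (kind == "trajectory_csv") {
    df <- utils::read.csv(path, nrows = 1)
    need <- c("particle_id", "frame", "x_um", "y_um")
    miss <- setdiff(need, names(df))
    if (length(miss))
      problems <- c(problems,
                    paste0("CSV missing column(s): ",
                           paste(miss, collapse = ", ")))
    sc <- sidecar_path(path)
    if (!file.exists(sc)) {
      problems <- c(problems, "metadata sidecar missing")
    } else {
      meta <- jsonlite::read_json(sc)   # keep explicit nulls visible
      for (key in c("fps", "pixel_size"))
        if (!key %in% names(meta))
          problems <- c(problems, paste0("sidecar missing key: ", key))
      if (is.null(meta$fps))
        problems <- c(problems, "sidecar fps must not be null")
    }
    if (!length(problems)) {
      ens <- read_trajectories(path)
      tmp <- tempfile(fileext = ".csv")
      on.exit(unlink(c(tmp, sidecar_path(tmp))), add = TRUE)
      write_trajectories(ens, tmp)
      ens2 <- read_trajectories(tmp)
      if (!isTRUE(all.equal(as.data.frame(ens), as.data.frame(ens2),
                            tolerance = 1e-12)))
        problems <- c(problems, "CSV round trip altered trajectory data")
    }
  } else if (kind == "json") {
    ok <- tryCatch({ jsonlite::read_json(path); TRUE },
                   error = function(e) conditionMessage(e))
    if (is.character(ok)) problems <- c(problems, ok)
  } else {
    problems <- "unrecognized file extension"
  }
  structure(list(path = path, kind = kind, ok = !length(problems),
                 problems = problems),
            class = "format_report")
}

#' @export
print.format_report <- function(x, ...) {
  cat(sprintf("<format_report> %s (%s): %s\n", x$path, x$kind,
              if (x$ok) "OK" else paste(x$problems, collapse = "; ")))
  invisible(x)
}
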