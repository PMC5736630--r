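#' Track every frame of an image stack
#'
#' Full localization chain on a video: per frame, [bandpass()] then
#' [locate_features()] then [filter_features()], followed by
#' [link_features()] across frames. Default thresholds are tuned to the
#' packaged renderer (7 px spots, SNR ~10) and are all overridable; every
#' effective value is attached to the result as attribute `params`.
#'
#' @param stack A [frame_stack()].
#' @param feature_diameter Odd spot extent in px.
#' @param noise_length Bandpass noise scale in px.
#' @param percentile_threshold Candidate intensity percentile.
#' @param min_mass,size_range,max_ecc Feature filter thresholds.
#' @param max_displacement,memory Linking parameters (px, frames).
#' @return A [traj_ensemble()] in um with attributes `params` and
#'   `counts` (features located / retained per stage).
#' @export
track_stack <- function(stack, feature_diameter = 7L, noise_length = 1,
                        percentile_threshold = 90, min_mass = 10000,
                        size_range = c(1, 4), max_ecc = 0.3,
                        max_displacement = 5, memory = 0L) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- dim(stack$frames)[1]
  feats <- vector("list", nf)
  n_located <- 0L
  rejected <- c(mass = 0L, size = 0L, ecc = 0L)
  for (i in seq_len(nf)) {
    bp <- bandpass(stack$frames[i, , ], noise_length, feature_diameter)
    fr <- locate_features(bp, feature_diameter, percentile_threshold)
    n_located <- n_located + nrow(fr)
    fr <- filter_features(fr, min_mass = min_mass, size_range = size_range,
                          max_ecc = max_ecc)
    rejected <- rejected + attr(fr, "rejected")
    if (nrow(fr)) feats[[i]] <- cbind(frame = i - 1L, fr)
  }
  feats <- do.call(rbind, feats)
  if (is.null(feats) || nrow(feats) == 0L)
    stop("no features retained; check filter thresholds")
  ens <- link_features(feats, max_displacement = max_displacement,
                       memory = memory, fps = stack$fps,
                       pixel_size = stack$pixel_size)
  attr(ens, "params") <- list(feature_diameter = feature_diameter,
                              noise_length = noise_length,
                              percentile_threshold = percentile_threshold,
                              min_mass = min_mass, size_range = size_range,
                              max_ecc = max_ecc,
                              max_displacement = max_displacement,
                              memory = memory)
  attr(ens, "counts") <- list(features_located = n_located,
                              features_retained = nrow(feats),
                              rejected = as.list(rejected),
                              trajectories = n_trajectories(ens))
  ens
}

#' Run the full analysis pipeline from a configuration list
#'
#' Orchestrates the stages end to end and writes every intermediate
#' artifact plus a run manifest. Two entry modes:
#'
#' * `mode = "scenario"`: simulate a packaged or custom aging scenario,
#'   write per-age trajectory CSVs, run the time-course analysis, write
#'   `summary.csv` and `timecourse.json`.
#' * `mode = "movie"`: simulate one configuration, render it to TIFF,
#'   track it, analyze the single age, write features/trajectories CSVs
#'   and `analysis.json`.
#'
#' Unknown configuration keys are rejected. The manifest echoes the full
#' effective configuration, records per-stage counts, warnings, and md5
#' checksums of every file written, and is written last.
#'
#' @param config Named list; see Details in the package vignette. Top-level
#'   keys: `mode`, `seed`, `out_dir`, and per-mode blocks `scenario` /
#'   `movie` / `analyze`.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  known <- c("mode", "seed", "out_dir", "scenario", "movie", "analyze")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  mode <- match.arg(config$mode, c("scenario", "movie"))
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  files <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  analyze_args <- config$analyze %||% list()
  counts <- list()
  results <- list()

  if (mode == "scenario") {
    sc <- config$scenario %||% list()
    scen <- if (!is.null(sc$file)) read_scenario(sc$file)
      else do.call(build_aging_scenario,
                   c(list(name = sc$name %||% "PAO1_like", seed = seed),
                     sc[setdiff(names(sc), c("name", "file"))]))
    ensembles <- simulate_scenario(scen)
    for (i in seq_along(ensembles)) {
      p <- file.path(out_dir, sprintf("trajectories_age%08d.csv",
                                      as.integer(scen$stanzas[[i]]$age_s)))
      write_trajectories(ensembles[[i]], p)
      files <- c(files, p, sidecar_path(p))
    }
    tc <- withCallingHandlers(
      do.call(analyze_timecourse, c(list(ensembles), analyze_args)),
      warning = function(w) { note(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    sp <- file.path(out_dir, "summary.csv")
    utils::write.csv(tc$summary, sp, row.names = FALSE, quote = FALSE)
    tp <- file.path(out_dir, "timecourse.json")
    jsonlite::write_json(list(scenario = scen$name,
                              transition_age = tc$transition_age,
                              subdiffusive_onset_age =
                                tc$subdiffusive_onset_age,
                              regimes = tc$summary$regime),
                         tp, auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, sp, tp)
    counts$ages_analyzed <- nrow(tc$summary)
    counts$trajectories <- sum(tc$summary$n_traj)
    results <- list(transition_age = tc$transition_age,
                    subdiffusive_onset_age = tc$subdiffusive_onset_age,
                    regimes = tc$summary$regime)
  } else {
    mv <- config$movie %||% list()
    cfg_args <- mv$sim %||% stop("config$movie$sim is required")
    cfg <- do.call(sim_config, c(cfg_args, list(seed = seed)))
    gt <- simulate_trajectories(cfg)
    gtp <- file.path(out_dir, "ground_truth.csv")
    write_trajectories(gt, gtp)
    render_args <- mv$render %||% list()
    stack <- withCallingHandlers(
      do.call(render_video, c(list(gt), render_args,
                              list(noise_seed = seed + 1L))),
      warning = function(w) { note(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    vp <- file.path(out_dir, "movie.tif")
    write_stack(stack, vp)
    track_args <- mv$track %||% list()
    ens <- do.call(track_stack, c(list(stack), track_args))
    trp <- file.path(out_dir, "trajectories.csv")
    write_trajectories(ens, trp)
    age <- withCallingHandlers(
      do.call(analyze_age, c(list(ens), analyze_args)),
      warning = function(w) { note(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    ap <- file.path(out_dir, "analysis.json")
    jsonlite::write_json(list(n = age$fit$exponent, d_um = age$fit$d_um,
                              regime = age$label$regime,
                              D_app = age$d_app, n_traj = age$n_traj),
                         ap, auto_unbox = TRUE, digits = NA)
    files <- c(files, gtp, sidecar_path(gtp), vp, sidecar_path_tif(vp),
               trp, sidecar_path(trp), ap)
    counts <- attr(ens, "counts")
    results <- list(n = age$fit$exponent, d_um = age$fit$d_um,
                    regime = age$label$regime)
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("ptmr")),
                   config = config, seed = seed,
                   counts = counts, results = results,
                   warnings = warnings_log,
                   checksums = as.list(tools::md5sum(sort(unique(files)))))
  mpath <- file.path(out_dir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  file.rename(tmp, mpath)     # atomic write
  invisible(manifest)
}
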