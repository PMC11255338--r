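#' Expected fraction of cells carrying a division-site marker
#'
#' Monte-Carlo estimate (via [sample_population_ages()]) of the percentage
#' of cells in an unsynchronized, exponentially growing population whose
#' age lies within `window_min` of division — i.e. the cells that would
#' show a marker residing at the division site for the final `window_min`
#' of the cell cycle. The analytic value `100 * (2^(window/Td) - 1)` and a
#' binomial standard error accompany the estimate.
#'
#' @param doubling_time_min Doubling time `Td`, minutes.
#' @param window_min Marker residence window before division, minutes;
#'   must not exceed `Td`.
#' @param n Simulated cells.
#' @param seed Integer seed.
#' @return Named list: `percent` (Monte-Carlo), `se_percent` (binomial SE),
#'   `analytic_percent`, `n`.
#' @examples
#' # ~5% of cells show a marker resident for the last 20 min of a 300-min cycle
#' age_model_fraction(300, 20, n = 10000, seed = 1)
#' @export
age_model_fraction <- function(doubling_time_min, window_min, n = 10000,
                               seed = NULL) {
  if (window_min < 0 || window_min > doubling_time_min) {
    stop("'window_min' must lie in [0, doubling_time_min]")
  }
  ages <- sample_population_ages(n, doubling_time_min, seed = seed)
  hit <- ages >= doubling_time_min - window_min
  p <- mean(hit)
  list(percent = 100 * p,
       se_percent = 100 * sqrt(p * (1 - p) / n),
       analytic_percent = 100 * (2^(window_min / doubling_time_min) - 1),
       n = n)
}

pipeline_modes <- c("snapshot", "timelapse", "motility", "kinetics", "age_model")

known_keys <- list(
  common = c("mode", "seed", "output_dir"),
  snapshot = c("n_cells", "polar_fractions", "noise_gaussian_sd",
               "poisson_scaling", "k_sd", "cap_depth_um", "pixel_size_um",
               "min_pixels", "write_tiff"),
  timelapse = c("n_movies", "frame_interval_min", "markers", "k_sd",
                "min_pixels", "cap_depth_um", "pixel_size_um",
                "baseline_frames", "k_burst"),
  motility = c("n_tracks", "reversal_rate_per_min", "heading_jitter_deg",
               "speed_um_min", "angle_threshold_deg", "persistence_frames"),
  kinetics = c("model", "true_params", "x_values", "replicates", "noise_sd"),
  age_model = c("doubling_time_min", "window_min", "n")
)

#' Run a reproducible simulate-and-quantify pipeline
#'
#' Single entry point orchestrating the package's stages from one
#' configuration (a named list or a YAML file path): generate synthetic
#' inputs, quantify them, and write tabular outputs plus a run manifest
#' (configuration echo and hash, seed, package version, output checksums)
#' into `output_dir`. Identical configuration and seed give identical
#' outputs. Unknown configuration keys are rejected before any computation.
#'
#' Modes: `"snapshot"` (scene -> per-cell polarity records + population
#' summary), `"timelapse"` (division movies -> event timing table),
#' `"motility"` (tracks -> per-track speeds/reversals + condition summary),
#' `"kinetics"` (simulated dataset -> model fit report), `"age_model"`
#' (Monte-Carlo marker-fraction estimate).
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the written file paths and the main
#'   result object of the mode.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$mode)) {
    stop("config must be a list (or YAML file) with a 'mode' key")
  }
  mode <- match.arg(config$mode, pipeline_modes)
  allowed <- c(known_keys$common, known_keys[[mode]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) for mode '", mode, "': ",
         paste(unknown, collapse = ", "))
  }
  out_dir <- config$output_dir %||% stop("config needs 'output_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  files <- character(0)
  result <- NULL

  if (mode == "snapshot") {
    sp <- scene_params(
      n_cells = config$n_cells %||% 50,
      polar_fractions = config$polar_fractions %||% c(0.15, 0.05),
      noise_gaussian_sd = config$noise_gaussian_sd %||% 5,
      poisson_scaling = config$poisson_scaling %||% 1,
      pixel_size_um = config$pixel_size_um %||% 0.1,
      seed = seed
    )
    scene <- make_snapshot_scene(sp)
    recs <- analyze_snapshot(
      scene$image, scene$mask,
      k_sd = config$k_sd %||% 2, min_pixels = config$min_pixels %||% 3L,
      cap_depth_um = config$cap_depth_um %||% 0.35,
      pixel_size_um = config$pixel_size_um %||% 0.1
    )
    summ <- population_summary(recs)
    files <- c(percell = file.path(out_dir, "cells.csv"),
               population = file.path(out_dir, "population.csv"),
               truth = file.path(out_dir, "truth.csv"))
    write.csv(recs, files["percell"], row.names = FALSE)
    write.csv(data.frame(class = names(summ$pattern_fractions),
                         fraction = unname(summ$pattern_fractions)),
              files["population"], row.names = FALSE)
    write.csv(scene$truth, files["truth"], row.names = FALSE)
    if (isTRUE(config$write_tiff)) {
      files <- c(files, image = file.path(out_dir, "scene.tif"),
                 mask = file.path(out_dir, "mask.tif"))
      write_image_stack(pmax(scene$image, 0), files["image"])
      write_image_stack(scene$mask, files["mask"])
    }
    result <- list(records = recs, summary = summ)
  } else if (mode == "timelapse") {
    n_movies <- config$n_movies %||% 10
    rows <- lapply(seq_len(n_movies), function(i) {
      mp <- movie_params(
        frame_interval_min = config$frame_interval_min %||% 5,
        markers = config$markers %||% "midcell_cluster",
        seed = seed * 1000L + i
      )
      what <- c("cluster", "burst")[c("midcell_cluster" %in% mp$markers,
                                      "biosensor" %in% mp$markers)]
      cbind(movie = i,
            analyze_division_movie(
              make_division_movie(mp), what = what,
              k_sd = config$k_sd %||% 2,
              min_pixels = config$min_pixels %||% 3L,
              cap_depth_um = config$cap_depth_um %||% 0.35,
              pixel_size_um = config$pixel_size_um %||% 0.1,
              baseline_frames = config$baseline_frames %||% 5L,
              k_burst = config$k_burst %||% 5))
    })
    result <- do.call(rbind, rows)
    files <- c(events = file.path(out_dir, "events.csv"))
    write.csv(result, files["events"], row.names = FALSE)
  } else if (mode == "motility") {
    tp <- track_params(
      n_tracks = config$n_tracks %||% 30,
      reversal_rate_per_min = config$reversal_rate_per_min %||% 2 / 15,
      heading_jitter_deg = config$heading_jitter_deg %||% 10,
      speed_um_min = config$speed_um_min %||% c(2, 0.5),
      seed = seed
    )
    tk <- make_tracks(tp)
    per <- analyze_tracks(
      tk$tracks,
      angle_threshold_deg = config$angle_threshold_deg %||% 120,
      persistence_frames = config$persistence_frames %||% 2L
    )
    moving <- per[per$moving, ]
    summ <- reversal_distribution(list(all = moving$n_reversals))
    files <- c(tracks = file.path(out_dir, "tracks.csv"),
               summary = file.path(out_dir, "summary.csv"))
    write.csv(per, files["tracks"], row.names = FALSE)
    write.csv(summ$summary, files["summary"], row.names = FALSE)
    result <- list(per_track = per, summary = summ)
  } else if (mode == "kinetics") {
    model <- config$model %||% "inhibition"
    dat <- make_kinetics_dataset(
      model = model,
      true_params = config$true_params %||%
        (if (model == "inhibition") list(V0 = 1, Ki = 15, h = 1.8)
         else list(Rmax = 1, KD = 3.5)),
      x_values = config$x_values %||%
        (if (model == "inhibition") c(0, 1, 3, 10, 30, 100, 300, 1000)
         else c(0, 0.5, 1, 2, 5, 10, 25, 50)),
      replicates = config$replicates %||% 3L,
      noise_sd = config$noise_sd %||% 0.05,
      seed = seed
    )
    fit <- if (model == "inhibition") fit_inhibition(dat) else fit_binding(dat)
    files <- c(data = file.path(out_dir, "kinetics_data.csv"),
               fit = file.path(out_dir, "fit_report.txt"))
    write.csv(dat, files["data"], row.names = FALSE)
    rep_lines <- utils::capture.output(print(fit))
    writeLines(rep_lines, files["fit"])
    result <- fit
  } else if (mode == "age_model") {
    result <- age_model_fraction(
      doubling_time_min = config$doubling_time_min %||% 300,
      window_min = config$window_min %||% 20,
      n = config$n %||% 10000, seed = seed
    )
    files <- c(age_model = file.path(out_dir, "age_model.csv"))
    write.csv(as.data.frame(result), files["age_model"], row.names = FALSE)
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    mode = mode, seed = seed,
    package_version = as.character(utils::packageVersion("polburst")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(files = c(files, config = cfg_file, manifest = manifest_file),
                 result = result))
}
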