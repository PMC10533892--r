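# End-to-end pipeline: simulate -> segment -> track -> quantify -> fit ->
# calibrate -> report, with a serializable config and a run manifest.

#' Pipeline configuration
#'
#' All knobs of the end-to-end run, fully serializable to JSON via
#' [save_pipeline_config()] / [load_pipeline_config()].
#'
#' @param movie path to the multi-page TIFF (sidecar JSON expected next to
#'   it).
#' @param out_dir output directory.
#' @param dose_response optional path to a dose-response CSV (columns
#'   `microdomain`, `concentration_uM`, `response`, `cell_id`); when given,
#'   standard curves are fitted and written.
#' @param background_radius,sigma preprocessing defaults (50 px rolling-ball
#'   radius, 2 px Gaussian sigma).
#' @param seg_channel,threshold,min_area_um2,refine segmentation knobs, see
#'   [segmentation_config()].
#' @param max_disp,max_gap linking gate (um) and gap bridging (frames).
#' @param population_preset `"HEK"` or `"MEF"`.
#' @param spot_radius spot population radius (um).
#' @param baseline_frames optional explicit 0-based baseline frames.
#' @param kinetics_population population whose mean trace is fit per pulse.
#' @param seed integer seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(movie, out_dir, dose_response = NULL,
                            background_radius = 50, sigma = 2,
                            seg_channel = "biosensor", threshold = "otsu",
                            min_area_um2 = 0.1, refine = "halfmax",
                            max_disp = 2, max_gap = 2,
                            population_preset = "HEK", spot_radius = 1.5,
                            baseline_frames = NULL,
                            kinetics_population = "proximal",
                            seed = 1L) {
  structure(list(movie = movie, out_dir = out_dir,
                 dose_response = dose_response,
                 background_radius = background_radius, sigma = sigma,
                 seg_channel = seg_channel, threshold = threshold,
                 min_area_um2 = min_area_um2, refine = refine,
                 max_disp = max_disp, max_gap = max_gap,
                 population_preset = population_preset,
                 spot_radius = spot_radius,
                 baseline_frames = baseline_frames,
                 kinetics_population = kinetics_population,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`. @param path JSON path.
#' @export
save_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

validate_pipeline_config <- function(config) {
  if (!file.exists(config$movie))
    mp_stop("movie not found: ", config$movie)
  sidecar <- paste0(tools::file_path_sans_ext(config$movie), ".json")
  if (!file.exists(sidecar))
    mp_stop("metadata sidecar not found: ", sidecar)
  if (!is.null(config$dose_response) && !file.exists(config$dose_response))
    mp_stop("dose-response file not found: ", config$dose_response)
  if (config$background_radius < 1 || config$sigma <= 0 ||
      config$max_disp <= 0 || config$max_gap < 0)
    mp_stop("pipeline parameters out of bounds")
  invisible(config)
}

write_csv_out <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Stages: load movie -> segment (background subtraction, smoothing,
#' threshold + half-max refinement) -> link tracks -> extract normalized
#' traces and morphology -> population summaries -> per-pulse kinetics of
#' the configured population's mean trace -> optional dose-response
#' calibration. Every intermediate is written as CSV/JSON under `out_dir`;
#' a manifest (config echo, seed, input checksums, per-stage row counts,
#' warnings, timings) is written last. Deterministic: identical config and
#' inputs give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) if (!quiet) message("[mitopulse] ", ...)
  counts <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    note(name, " done (", timings[[name]], " s)")
    res
  }

  movie <- stage("load", read_movie_tiff(config$movie))
  meta <- movie$meta

  seg_cfg <- segmentation_config(channel = config$seg_channel,
                                 background_radius = config$background_radius,
                                 sigma = config$sigma,
                                 threshold = config$threshold,
                                 min_area_um2 = config$min_area_um2,
                                 refine = config$refine)
  per_frame <- stage("segment", segment_movie(movie, seg_cfg))
  counts$segment <- sum(vapply(per_frame, function(m)
    if (is.null(m)) 0L else nrow(m), 0L))
  dropped <- attr(per_frame, "dropped_frames")
  if (length(dropped))
    warnings_log <- c(warnings_log,
                      paste0("segment: dropped artifact frame ", dropped))

  tracks <- stage("track", link_tracks(per_frame, max_disp = config$max_disp,
                                       max_gap = config$max_gap,
                                       frame_interval = meta$frame_interval))
  counts$tracks <- length(unique(tracks$track_id))
  counts$track_rows <- write_csv_out(tracks,
                                     file.path(config$out_dir, "tracks.csv"))

  pop_cfg <- population_config(config$population_preset,
                               spot_radius = config$spot_radius)
  traces <- stage("quantify", extract_traces(
    tracks, meta, pop_cfg, channel = "biosensor",
    baseline_frames = config$baseline_frames))
  counts$trace_rows <- write_csv_out(traces,
                                     file.path(config$out_dir, "traces.csv"))

  morph <- tracks[, c("track_id", "frame", "time_s", "area_um2")]
  morph$form_factor <- form_factor(tracks$perimeter_um, tracks$area_um2)
  morph$population <- traces$population[match(
    paste(morph$track_id, morph$frame),
    paste(traces$track_id, traces$frame))]
  morph$population[is.na(morph$population)] <- "other"
  counts$morph_rows <- write_csv_out(morph,
                                     file.path(config$out_dir, "morphology.csv"))

  summ <- stage("summarize", population_summary(
    data.frame(frame = traces$frame, value = traces$value - 1,
               population = traces$population), smooth_window = 3L))
  counts$summary_rows <- write_csv_out(
    summ, file.path(config$out_dir, "population_summary.csv"))

  kin <- stage("kinetics", pipeline_kinetics(traces, meta,
                                             config$kinetics_population))
  counts$kinetics_rows <- write_csv_out(kin,
                                        file.path(config$out_dir, "kinetics.csv"))

  if (!is.null(config$dose_response)) {
    dr <- read.csv(config$dose_response, stringsAsFactors = FALSE)
    curves <- stage("calibrate", {
      lapply(split(dr, dr$microdomain), fit_standard_curve)
    })
    jsonlite::write_json(
      lapply(curves, function(cu) unclass(cu)),
      file.path(config$out_dir, "standard_curves.json"),
      auto_unbox = TRUE, digits = NA)
    counts$curves <- length(curves)
  }

  manifest <- list(
    package = "mitopulse",
    version = as.character(utils::packageVersion("mitopulse")),
    seed = config$seed,
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(
      c(config$movie, paste0(tools::file_path_sans_ext(config$movie), ".json")))),
    row_counts = counts,
    dropped_frames = as.integer(dropped),
    warnings = warnings_log,
    timings_s = timings)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# Per-pulse kinetics on the mean trace of one population: plateau-decay fit,
# half-rise time and AUC between each pulse and the next (or the end).
pipeline_kinetics <- function(traces, meta, population = "proximal") {
  ev <- meta$stim_events
  if (is.null(ev) || !nrow(ev)) return(data.frame())
  sel <- traces$population %in% c(population, "spot")
  if (!any(sel)) return(data.frame())
  sub <- traces[sel, , drop = FALSE]
  mean_tr <- stats::aggregate(value ~ time_s, sub, mean)
  mean_tr <- mean_tr[order(mean_tr$time_s), ]
  stim_times <- sort(ev$frame) * meta$frame_interval
  out <- lapply(seq_along(stim_times), function(j) {
    lo <- stim_times[j]
    hi <- if (j < length(stim_times)) stim_times[j + 1] else Inf
    seg <- mean_tr$time_s >= lo - 5 * meta$frame_interval & mean_tr$time_s < hi
    tt <- mean_tr$time_s[seg]; vv <- mean_tr$value[seg]
    fit <- tryCatch(fit_plateau_decay(tt, vv, stim_time = lo),
                    error = function(e) NULL)
    th <- tryCatch(t_half_rise(tt, vv, stim_time = lo),
                   error = function(e) list(T_half = NA_real_,
                                            peak_value = NA_real_))
    a <- tryCatch(auc_trace(tt, vv, window = c(lo, max(tt)), baseline_ref = 1),
                  error = function(e) NA_real_)
    data.frame(pulse = j, population = population,
               n_points = length(tt),
               plateau = if (is.null(fit)) NA_real_ else fit$plateau,
               t0_s = if (is.null(fit)) NA_real_ else fit$t0,
               K_per_min = if (is.null(fit)) NA_real_ else fit$K,
               baseline = if (is.null(fit)) NA_real_ else fit$baseline,
               RSS = if (is.null(fit)) NA_real_ else fit$RSS,
               converged = if (is.null(fit)) FALSE else fit$converged,
               T_half_s = th$T_half, peak_value = th$peak_value,
               auc = a, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Tiny simulation world: 20 frames, 5 small mitochondria in a ~10 um field
# (roomy enough that placement succeeds for any seed), one pulse, noise on.
tiny_sim_params <- function(seed) {
  sim_params(image_shape = c(192L, 192L), n_frames = 20L, n_mitos = 5L,
             mito_length_range = c(0.7, 1.2), stim_frames = 8L,
             plateau_duration = 30, rng_seed = seed)
}

#' Write a self-contained synthetic fixture
#'
#' Builds a synthetic dataset (movie TIFF + metadata sidecar + ground-truth
#' CSV/JSON + a dose-response CSV drawn from a known standard curve) used by
#' the test suite and the worked examples.
#'
#' `tiny` is a 20-frame, 5-mitochondrion movie with shot and read noise that
#' runs through the whole pipeline in seconds; `standard` is the full stated
#' world -- 230 frames at 5 s, 20 mitochondria, two 5-s stimulation pulses
#' (frames 24 and 120) and noise turned off so that segmentation and
#' tracking can be checked against ground truth exactly.
#'
#' @param dir fixture directory (created).
#' @param size `"tiny"` or `"standard"`.
#' @param seed integer seed.
#' @return list with paths (`movie`, `truth_csv`, `truth_json`,
#'   `dose_response`) and the in-memory `truth` and `params`.
#' @export
make_fixture <- function(dir, size = c("tiny", "standard"), seed = 1L) {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (size == "tiny") tiny_sim_params(seed) else
    sim_params(rng_seed = seed, noise_shot = FALSE, noise_read_sigma = 0)
  sim <- simulate_movie(params)
  movie_path <- file.path(dir, "movie.tif")
  write_movie_tiff(sim$movie, movie_path)
  truth_csv <- file.path(dir, "ground_truth.csv")
  write.csv(sim$truth$objects, truth_csv, row.names = FALSE)
  truth_json <- file.path(dir, "sim_params.json")
  pj <- unclass(sim$truth$params)
  pj$response_range <- as.list(pj$response_range)
  jsonlite::write_json(pj, truth_json, auto_unbox = TRUE, digits = NA)

  true_curve <- standard_curve("matrix", bottom = 1, top = 6.5, EC50 = 1.4,
                               hill = 1.8)
  dr <- simulate_dose_response(true_curve,
                               concentrations = c(0, 0.25, 0.5, 1, 2.5, 5, 10, 25),
                               cv = 0.05, n_cells = 10L, seed = seed + 1000L)
  dose_path <- file.path(dir, "dose_response.csv")
  write.csv(dr, dose_path, row.names = FALSE)
  list(movie = movie_path, truth_csv = truth_csv, truth_json = truth_json,
       dose_response = dose_path, truth = sim$truth, params = params)
}
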