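# Track-to-trace conversion, morphology metrics, distances and
# subpopulation classification.

#' Population classification configuration
#'
#' Mitochondria are classified relative to the cell's maximum
#' mitochondrion-to-stimulation-point distance M: proximal if d/M is below
#' `proximal_frac`, distal if above `distal_frac`, and additionally "spot" if
#' within `spot_radius` um of the stimulation point (spot is a subset of the
#' proximal side, reported separately). The HEK preset uses 30%/70%; the MEF
#' preset 20%/50%.
#'
#' @param preset `"HEK"` or `"MEF"`.
#' @param proximal_frac,distal_frac fractional distance thresholds
#'   (0 < proximal < distal < 1); override the preset when given.
#' @param spot_radius absolute spot radius in um.
#' @return a `population_config` list.
#' @export
population_config <- function(preset = c("HEK", "MEF"), proximal_frac = NULL,
                              distal_frac = NULL, spot_radius = 1.5) {
  preset <- match.arg(preset)
  def <- if (preset == "HEK") c(0.30, 0.70) else c(0.20, 0.50)
  pf <- if (is.null(proximal_frac)) def[1] else proximal_frac
  df <- if (is.null(distal_frac)) def[2] else distal_frac
  if (!(pf > 0 && pf < df && df < 1))
    mp_stop("need 0 < proximal_frac < distal_frac < 1")
  if (spot_radius <= 0) mp_stop("spot_radius must be positive")
  structure(list(preset = preset, proximal_frac = pf, distal_frac = df,
                 spot_radius = spot_radius), class = "population_config")
}

# Label a vector of distances given the per-cell maximum distance taken over
# the same vector. Used both by classify_population and by the simulator's
# ground-truth labels.
classify_distances <- function(d, config, M = max(d)) {
  if (M <= 0) mp_stop("maximum distance M is zero: cannot classify")
  lab <- rep("other", length(d))
  lab[d / M < config$proximal_frac] <- "proximal"
  lab[d / M > config$distal_frac] <- "distal"
  lab[d < config$spot_radius] <- "spot"
  lab
}

#' Area-normalized intensity series of one track
#'
#' Per-frame summed intensity divided by the object's area in that frame
#' (counts/um^2), removing artifacts from focal drift and size changes.
#'
#' @param track data.frame rows of one track (from [link_tracks()]).
#' @param channel channel name whose `sum_<channel>` column is used.
#' @return numeric vector, one value per frame of the track.
#' @export
area_normalize <- function(track, channel = "biosensor") {
  col <- paste0("sum_", channel)
  if (!col %in% names(track)) mp_stop("no column ", col, " in track")
  if (any(track$area_um2 <= 0)) mp_stop("non-positive area in track")
  track[[col]] / track$area_um2
}

#' Baseline normalization (F/F0 or dF/F)
#'
#' Divides a series by the mean of its pre-stimulation baseline window.
#'
#' @param values numeric series.
#' @param baseline_idx integer indices (1-based) of the baseline window.
#' @param dff logical; `TRUE` returns dF/F = F/F0 - 1.
#' @return normalized series.
#' @export
baseline_normalize <- function(values, baseline_idx, dff = FALSE) {
  if (!length(baseline_idx)) mp_stop("empty baseline window")
  b <- mean(values[baseline_idx])
  if (!is.finite(b) || b <= 0) mp_stop("baseline mean must be positive")
  out <- values / b
  if (dff) out - 1 else out
}

#' Ratiometric biosensor trace (R/R0)
#'
#' Per-frame ratio of the 488-excitation emission to the 405-excitation
#' emission, normalized to the baseline window. A loss factor common to both
#' channels (focus drift, bleaching of a shared fluorophore) cancels.
#'
#' @param series_488,series_405 aligned numeric series.
#' @param baseline_idx baseline window indices.
#' @return R/R0 series.
#' @export
ratiometric_trace <- function(series_488, series_405, baseline_idx) {
  if (length(series_488) != length(series_405))
    mp_stop("channel series must be aligned")
  if (any(series_405 <= 0)) mp_stop("405-channel values must be positive")
  baseline_normalize(series_488 / series_405, baseline_idx)
}

#' Quench-ratio trace (sensor / reference)
#'
#' Baseline-normalized ratio of a compartment-targeted sensor to a cytosolic
#' reference fluorophore; used as a localization readout when a membrane-
#' impermeant quencher reaches compartments at rates ordered by how many
#' membranes enclose them.
#'
#' @param sensor_series,reference_series aligned per-cell series.
#' @param baseline_idx baseline window indices.
#' @return normalized ratio series.
#' @export
quench_ratio_trace <- function(sensor_series, reference_series, baseline_idx) {
  if (length(sensor_series) != length(reference_series))
    mp_stop("series must be aligned")
  if (any(reference_series <= 0)) mp_stop("reference values must be positive")
  baseline_normalize(sensor_series / reference_series, baseline_idx)
}

#' Per-frame Euclidean distance of a track to the stimulation point
#'
#' @param track data.frame with `x_um`, `y_um`.
#' @param stim_point length-2 numeric (x, y) in um.
#' @return numeric vector of distances (um).
#' @export
distance_to_stim <- function(track, stim_point) {
  if (is.null(stim_point) || length(stim_point) != 2L)
    mp_stop("stim_point must be (x, y) in um")
  sqrt((track$x_um - stim_point[1])^2 + (track$y_um - stim_point[2])^2)
}

#' Classify tracks into spot/proximal/distal/other populations
#'
#' The per-cell maximum distance M is the maximum over all tracks of the
#' distance to the stimulation point within the reference window (by default
#' the first stimulation frame). Labels are frozen per track from the
#' reference window: population membership does not change over the
#' recording.
#'
#' @param tracks data.frame from [link_tracks()] (needs `track_id`, `frame`,
#'   `x_um`, `y_um`).
#' @param stim_point (x, y) um.
#' @param config a [population_config()].
#' @param reference_frames 0-based frame indices of the reference window.
#' @return data.frame with `track_id`, `dist_um` (reference distance),
#'   `population`.
#' @export
classify_population <- function(tracks, stim_point,
                                config = population_config("HEK"),
                                reference_frames = NULL) {
  if (!nrow(tracks)) mp_stop("no tracks to classify")
  d_all <- distance_to_stim(tracks, stim_point)
  if (is.null(reference_frames)) reference_frames <- min(tracks$frame)
  sel <- tracks$frame %in% reference_frames
  if (!any(sel)) mp_stop("no measurements in the reference window")
  ref <- data.frame(track_id = tracks$track_id[sel], d = d_all[sel])
  ref <- stats::aggregate(d ~ track_id, ref, mean)
  M <- max(ref$d)
  data.frame(track_id = ref$track_id, dist_um = ref$d,
             population = classify_distances(ref$d, config, M),
             stringsAsFactors = FALSE)
}

#' Form factor
#'
#' `FF = perimeter^2 / (4 pi area)`: 1 for a circle (isoperimetric equality),
#' larger for elongated or complex shapes. Dimensionless, hence invariant to
#' spatial rescaling.
#'
#' @param perimeter,area positive numerics (consistent units).
#' @return form factor value(s).
#' @export
form_factor <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0))
    mp_stop("perimeter and area must be positive")
  perimeter^2 / (4 * pi * area)
}

#' Centered moving average (display smoothing only)
#'
#' @param x numeric series. @param window odd window length in samples.
#' @return smoothed series (edges use the available samples).
#' @export
moving_average <- function(x, window = 3L) {
  n <- length(x)
  hw <- window %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - hw):min(n, i + hw)]), 0.0)
}

#' Per-population, per-frame summary of traces or metrics
#'
#' @param df tidy data.frame with columns `frame`, `value`, `population`
#'   (and anything else, ignored).
#' @param exclude populations excluded from the proportion denominator
#'   (none by default: proportions over all listed rows sum to 1).
#' @param smooth_window if not NULL, adds a `mean_smoothed` column (centered
#'   moving average per population); the raw `mean` stays untouched, matching
#'   the rule that smoothing is for display only.
#' @return data.frame: population, frame, n, mean, sem, proportion
#'   (n / total objects in that frame, after exclusions).
#' @export
population_summary <- function(df, exclude = character(),
                               smooth_window = NULL) {
  df <- df[!df$population %in% exclude, , drop = FALSE]
  if (!nrow(df)) mp_stop("no data after exclusions")
  pops <- sort(unique(df$population))
  frames <- sort(unique(df$frame))
  tot <- table(factor(df$frame, levels = frames))
  out <- do.call(rbind, lapply(pops, function(p) {
    sub <- df[df$population == p, , drop = FALSE]
    if (!nrow(sub)) {
      mp_warn("population ", p, " is empty; omitted")
      return(NULL)
    }
    agg_n <- tapply(sub$value, factor(sub$frame, levels = frames), length)
    agg_m <- tapply(sub$value, factor(sub$frame, levels = frames), mean)
    agg_s <- tapply(sub$value, factor(sub$frame, levels = frames),
                    function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0)
    n <- ifelse(is.na(agg_n), 0L, agg_n)
    data.frame(population = p, frame = frames, n = as.integer(n),
               mean = as.numeric(agg_m), sem = as.numeric(agg_s),
               proportion = as.integer(n) / as.numeric(tot),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(smooth_window)) {
    out$mean_smoothed <- NA_real_
    for (p in unique(out$population)) {
      sel <- out$population == p
      out$mean_smoothed[sel] <- moving_average(out$mean[sel], smooth_window)
    }
  }
  rownames(out) <- NULL
  out
}

#' Tidy normalized traces for all tracks of a movie
#'
#' Combines [area_normalize()], [baseline_normalize()],
#' [distance_to_stim()] and [classify_population()] into the tidy trace
#' table the kinetics stage consumes.
#'
#' @param tracks data.frame from [link_tracks()].
#' @param meta an `acquisition_meta` (for stimulation point/events and frame
#'   interval).
#' @param config a [population_config()].
#' @param channel biosensor channel name.
#' @param baseline_frames 0-based baseline frame indices; default all frames
#'   before the first stimulation, minus the first 4 frames (early-drift
#'   guard), falling back to all pre-stimulation frames for short recordings.
#' @param dff logical, emit dF/F instead of F/F0.
#' @return data.frame: track_id, frame, time_s, value, dist_um, population.
#' @export
extract_traces <- function(tracks, meta, config = population_config("HEK"),
                           channel = "biosensor", baseline_frames = NULL,
                           dff = FALSE) {
  if (!nrow(tracks)) mp_stop("no tracks")
  stim_frames <- if (!is.null(meta$stim_events) && nrow(meta$stim_events))
    sort(meta$stim_events$frame) else integer()
  if (is.null(baseline_frames)) {
    first_stim <- if (length(stim_frames)) stim_frames[1] else
      max(tracks$frame) + 1L
    baseline_frames <- setdiff(seq_len(first_stim) - 1L, 0:3)
    if (!length(baseline_frames)) baseline_frames <- seq_len(first_stim) - 1L
  }
  labels <- classify_population(tracks, meta$stim_point, config,
                                reference_frames =
                                  if (length(stim_frames)) stim_frames[1] else NULL)
  out <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    bidx <- which(tr$frame %in% baseline_frames)
    if (!length(bidx)) return(NULL)   # track born after baseline: no F0
    dens <- area_normalize(tr, channel)
    val <- baseline_normalize(dens, bidx, dff = dff)
    data.frame(track_id = tr$track_id, frame = tr$frame,
               time_s = tr$time_s, value = val,
               dist_um = distance_to_stim(tr, meta$stim_point),
               stringsAsFactors = FALSE)
  }))
  out$population <- labels$population[match(out$track_id, labels$track_id)]
  out$population[is.na(out$population)] <- "other"
  rownames(out) <- NULL
  out
}

#' Photosensitizer-expression normalization of whole-cell responses
#'
#' Divides a cell's biosensor response amplitude by its mean photosensitizer
#' signal over the pre-stimulation window, so cells expressing more
#' photosensitizer (hence generating more ROS per pulse) are comparable.
#'
#' @param response_amplitude per-cell response amplitude(s).
#' @param kr_baseline per-cell mean pre-stimulation photosensitizer
#'   signal(s), > 0.
#' @return normalized amplitude(s).
#' @export
normalize_kr_expression <- function(response_amplitude, kr_baseline) {
  if (any(kr_baseline <= 0)) mp_stop("photosensitizer baseline must be positive")
  response_amplitude / kr_baseline
}
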