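# Synthetic two-channel photostimulation movies with ground truth.
#
# Geometry: mitochondria are capsules (rectangle + semicircular caps) defined
# by end-to-end length L, width W and orientation. Coordinates are in um with
# the origin at the centre of the top-left pixel; pixel (row i, col j) has
# centre (x = j * pixel_size, y = i * pixel_size). Pixel indices are 0-based
# in all ground-truth records.

capsule_area <- function(length, width) {
  width * pmax(0, length - width) + pi * (width / 2)^2
}

capsule_perimeter <- function(length, width) {
  2 * pmax(0, length - width) + pi * width
}

# Shortest distance between two segments (each given as center, unit axis,
# half-length); used for the hard-core exclusion between capsules.
segment_distance <- function(c1, u1, h1, c2, u2, h2) {
  # sample-based min distance: exact enough for a clearance check
  s <- seq(-1, 1, length.out = 9)
  p1 <- cbind(c1[1] + s * h1 * u1[1], c1[2] + s * h1 * u1[2])
  p2 <- cbind(c2[1] + s * h2 * u2[1], c2[2] + s * h2 * u2[2])
  min(sqrt(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2))
}

capsule_clearance <- function(geo, i, j) {
  d <- segment_distance(c(geo$x[i], geo$y[i]), c(cos(geo$theta[i]), sin(geo$theta[i])),
                        geo$half_axis[i],
                        c(geo$x[j], geo$y[j]), c(cos(geo$theta[j]), sin(geo$theta[j])),
                        geo$half_axis[j])
  d - (geo$width[i] + geo$width[j]) / 2
}

# Render one capsule's pixel coverage into an accumulator matrix.
# Linear 1-px anti-aliasing band across the boundary.
render_capsule <- function(acc, x, y, theta, length, width, amplitude, pixel_size) {
  h <- nrow(acc); w <- ncol(acc)
  half_axis <- max(0, (length - width) / 2)
  halfw <- width / 2
  pad <- halfw + 1.5 * pixel_size
  ux <- cos(theta); uy <- sin(theta)
  ex <- abs(ux) * half_axis + pad; ey <- abs(uy) * half_axis + pad
  j0 <- max(0L, floor((x - ex) / pixel_size)); j1 <- min(w - 1L, ceiling((x + ex) / pixel_size))
  i0 <- max(0L, floor((y - ey) / pixel_size)); i1 <- min(h - 1L, ceiling((y + ey) / pixel_size))
  if (j1 < j0 || i1 < i0) return(acc)
  jj <- j0:j1; ii <- i0:i1
  px <- jj * pixel_size - x
  py <- ii * pixel_size - y
  # distance from pixel centres to the axis segment
  gx <- matrix(px, nrow = length(ii), ncol = length(jj), byrow = TRUE)
  gy <- matrix(py, nrow = length(ii), ncol = length(jj))
  tproj <- gx * ux + gy * uy
  tproj <- pmin(pmax(tproj, -half_axis), half_axis)
  dx <- gx - tproj * ux
  dy <- gy - tproj * uy
  dist <- sqrt(dx^2 + dy^2)
  cov <- pmin(1, pmax(0, 0.5 + (halfw - dist) / pixel_size))
  acc[ii + 1L, jj + 1L] <- acc[ii + 1L, jj + 1L] + amplitude * cov
  acc
}

#' Simulate a two-channel photostimulation movie with ground truth
#'
#' Renders `n_mitos` capsule-shaped mitochondria drifting by Brownian motion
#' (with reflecting boundaries and a hard-core exclusion that preserves the
#' stated minimum clearance) over `n_frames` frames in two channels:
#'
#' * biosensor: per-mitochondrion signal density follows the plateau-then-
#'   decay response template; at each stimulation pulse the fractional rise is
#'   `A(d) = A0 * max(0, 1 - d/d_max)` with `d` the distance from that
#'   mitochondrion to the stimulation point at the pulse frame.
#' * photosensitizer: density is multiplied by
#'   `1 - bleach_fraction * max(0, 1 - d/d_max)` at each pulse (cumulative
#'   photobleaching).
#'
#' Mitochondria within 5 um of the stimulation point transiently elongate
#' after each pulse (half-sine stretch of the major axis up to
#' `elongation_factor`, width unchanged, signal density unchanged so that
#' area-normalized intensity is unaffected). Poisson shot noise and Gaussian
#' read noise are applied last; ground truth records the noiseless values.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `movie` (a `movie_stack`: `data` array
#'   `[H, W, frame, channel]`, channels `biosensor`, `photosensitizer`, plus
#'   acquisition metadata) and `truth` (a `ground_truth`: `objects` data frame
#'   with one row per frame and mitochondrion, and the `params` echo).
#' @export
simulate_movie <- function(params) {
  p <- validate_sim_params(params)
  set.seed(p$rng_seed)
  h <- p$image_shape[1]; w <- p$image_shape[2]
  fov <- c(w, h) * p$pixel_size          # (x extent, y extent)
  d_max <- unname(p$response_range[p$microdomain])
  times <- (seq_len(p$n_frames) - 1L) * p$frame_interval
  stim_times <- p$stim_frames * p$frame_interval

  # --- placement with clearance (elongation growth reserved up front) ---
  n <- p$n_mitos
  growth <- (p$elongation_factor - 1) * p$mito_length_range[2]
  place_clear <- p$min_clearance + growth
  geo <- list(x = numeric(n), y = numeric(n), theta = numeric(n),
              len = numeric(n), len0 = numeric(n), width = numeric(n),
              half_axis = numeric(n))
  if (n > 0L) {
    for (i in seq_len(n)) {
      li <- runif(1, p$mito_length_range[1], p$mito_length_range[2])
      wi <- runif(1, p$mito_width_range[1], min(p$mito_width_range[2], li))
      # reserve room for the elongation transient at the boundary
      margin <- li * p$elongation_factor / 2 + wi / 2 + 2 * p$pixel_size
      ok <- FALSE
      for (try in seq_len(2000L)) {
        if (i == 1L && try <= 50L) {
          # the stimulation protocol targets a predetermined spot ON a
          # mitochondrion: centre the first one at/near the stim point
          jit <- if (try == 1L) c(0, 0) else rnorm(2, 0, 0.3)
          xi <- min(max(p$stim_point[1] + jit[1], margin), fov[1] - margin)
          yi <- min(max(p$stim_point[2] + jit[2], margin), fov[2] - margin)
        } else {
          xi <- runif(1, margin, fov[1] - margin)
          yi <- runif(1, margin, fov[2] - margin)
        }
        ti <- runif(1, 0, pi)
        geo$x[i] <- xi; geo$y[i] <- yi; geo$theta[i] <- ti
        geo$len[i] <- li; geo$width[i] <- wi
        geo$half_axis[i] <- max(0, (li - wi) / 2)
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            if (capsule_clearance(geo, i, j) < place_clear) { ok <- FALSE; break }
          }
        }
        if (ok) break
      }
      if (!ok) mp_stop("could not place mitochondria without overlap: ",
                       "object density exceeds the packing limit")
      geo$len0[i] <- li
    }
  }

  # --- per-frame positions (Brownian, reflecting, hard-core) ---
  xs <- matrix(0, p$n_frames, max(n, 1L))
  ys <- matrix(0, p$n_frames, max(n, 1L))
  if (n > 0L) {
    xs[1, seq_len(n)] <- geo$x; ys[1, seq_len(n)] <- geo$y
    margin <- geo$len0 * p$elongation_factor / 2 + geo$width / 2 +
      2 * p$pixel_size
    if (p$n_frames > 1L) for (f in 2:p$n_frames) {
      for (i in seq_len(n)) {
        reflect1 <- function(v, lo, hi) {
          if (v < lo) v <- 2 * lo - v
          if (v > hi) v <- 2 * hi - v
          min(max(v, lo), hi)
        }
        prop_x <- reflect1(geo$x[i] + rnorm(1, 0, p$motion_sigma),
                           margin[i], fov[1] - margin[i])
        prop_y <- reflect1(geo$y[i] + rnorm(1, 0, p$motion_sigma),
                           margin[i], fov[2] - margin[i])
        old_x <- geo$x[i]; old_y <- geo$y[i]
        geo$x[i] <- prop_x; geo$y[i] <- prop_y
        if (n > 1L) {
          for (j in seq_len(n)[-i]) {
            if (capsule_clearance(geo, i, j) < p$min_clearance) {
              geo$x[i] <- old_x; geo$y[i] <- old_y  # reject step
              break
            }
          }
        }
      }
      xs[f, seq_len(n)] <- geo$x; ys[f, seq_len(n)] <- geo$y
    }
  }

  # --- per-mito kinetic factors ---
  # distance at each pulse frame sets that pulse's amplitude / bleach
  bio_factor <- matrix(1, p$n_frames, max(n, 1L))
  kr_factor <- matrix(1, p$n_frames, max(n, 1L))
  elong <- matrix(1, p$n_frames, max(n, 1L))
  d_truth <- matrix(0, p$n_frames, max(n, 1L))
  if (n > 0L) {
    for (i in seq_len(n)) {
      d_truth[, i] <- sqrt((xs[, i] - p$stim_point[1])^2 +
                           (ys[, i] - p$stim_point[2])^2)
      if (length(p$stim_frames)) {
        d_pulse <- d_truth[p$stim_frames + 1L, i]
        A_pulse <- response_attenuation(d_pulse, p$response_amplitude, d_max)
        bio_factor[, i] <- simulate_trace_multi(
          times, baseline = 1, A = A_pulse,
          plateau_duration = p$plateau_duration, K = p$decay_rate,
          stim_times = stim_times)
        shape <- pmax(0, 1 - d_pulse / d_max)
        for (jp in seq_along(stim_times)) {
          kr_factor[times >= stim_times[jp], i] <-
            kr_factor[times >= stim_times[jp], i] *
            (1 - p$bleach_fraction * shape[jp])
          if (d_pulse[jp] < 5) {  # near-spot transient elongation
            rel <- (times - stim_times[jp]) / p$elongation_duration
            win <- rel >= 0 & rel <= 1
            stretch <- 1 + (p$elongation_factor - 1) * sin(pi * rel[win])
            elong[win, i] <- pmax(elong[win, i], stretch)
          }
        }
      }
    }
  }

  # --- render + ground truth ---
  px_area <- p$pixel_size^2
  data <- array(0, dim = c(h, w, p$n_frames, 2),
                dimnames = list(NULL, NULL, NULL,
                                c("biosensor", "photosensitizer")))
  rows <- vector("list", p$n_frames)
  ref_frame <- if (length(p$stim_frames)) p$stim_frames[1] + 1L else 1L
  safe_labels <- function(d, cfg) {
    # degenerate scene (every object at the stim point): fall back to the
    # absolute spot rule, since the relative thresholds need M > 0
    if (max(d) > 0) classify_distances(d, cfg)
    else ifelse(d < cfg$spot_radius, "spot", "other")
  }
  labels <- if (n > 0L)
    safe_labels(d_truth[ref_frame, seq_len(n)], population_config("HEK"))
  else character()
  labels_mef <- if (n > 0L)
    safe_labels(d_truth[ref_frame, seq_len(n)], population_config("MEF"))
  else character()
  for (f in seq_len(p$n_frames)) {
    bio <- matrix(p$background_level, h, w)
    kr <- matrix(p$background_level, h, w)
    if (n > 0L) {
      len_f <- geo$len0 * elong[f, seq_len(n)]
      for (i in seq_len(n)) {
        bio <- render_capsule(bio, xs[f, i], ys[f, i], geo$theta[i], len_f[i],
                              geo$width[i],
                              p$baseline_biosensor * bio_factor[f, i],
                              p$pixel_size)
        kr <- render_capsule(kr, xs[f, i], ys[f, i], geo$theta[i], len_f[i],
                             geo$width[i],
                             p$baseline_photosensitizer * kr_factor[f, i],
                             p$pixel_size)
      }
      area_um2 <- capsule_area(len_f, geo$width[seq_len(n)])
      rows[[f]] <- data.frame(
        frame = f - 1L, true_id = seq_len(n),
        x_um = xs[f, seq_len(n)], y_um = ys[f, seq_len(n)],
        area_um2 = area_um2,
        perimeter_um = capsule_perimeter(len_f, geo$width[seq_len(n)]),
        major_um = len_f, minor_um = geo$width[seq_len(n)],
        dist_um = d_truth[f, seq_len(n)],
        population = labels, population_mef = labels_mef,
        bio_density = p$baseline_biosensor * bio_factor[f, seq_len(n)],
        kr_density = p$baseline_photosensitizer * kr_factor[f, seq_len(n)],
        bio_total = p$baseline_biosensor * bio_factor[f, seq_len(n)] *
          area_um2 / px_area,
        kr_total = p$baseline_photosensitizer * kr_factor[f, seq_len(n)] *
          area_um2 / px_area,
        stringsAsFactors = FALSE
      )
    }
    if (p$noise_shot) {
      bio <- matrix(rpois(h * w, pmax(bio, 0)), h, w)
      kr <- matrix(rpois(h * w, pmax(kr, 0)), h, w)
    }
    if (p$noise_read_sigma > 0) {
      bio <- bio + rnorm(h * w, 0, p$noise_read_sigma)
      kr <- kr + rnorm(h * w, 0, p$noise_read_sigma)
    }
    if (p$noise_shot || p$noise_read_sigma > 0) {
      bio <- pmin(pmax(round(bio), 0), 65535)
      kr <- pmin(pmax(round(kr), 0), 65535)
    }
    data[, , f, 1] <- bio
    data[, , f, 2] <- kr
  }

  meta <- acquisition_meta(
    pixel_size = p$pixel_size, frame_interval = p$frame_interval,
    stim_point = p$stim_point,
    stim_events = data.frame(frame = p$stim_frames,
                             duration_s = rep(p$stim_duration_s,
                                              length(p$stim_frames))),
    channel_roles = c(biosensor = "biosensor_488",
                      photosensitizer = "photosensitizer_561"))
  movie <- structure(list(data = data, meta = meta), class = "movie_stack")
  objects <- if (n > 0L) do.call(rbind, rows) else
    data.frame(frame = integer(), true_id = integer(), x_um = numeric(),
               y_um = numeric(), area_um2 = numeric(), perimeter_um = numeric(),
               major_um = numeric(), minor_um = numeric(), dist_um = numeric(),
               population = character(), population_mef = character(),
               bio_density = numeric(),
               kr_density = numeric(), bio_total = numeric(),
               kr_total = numeric(), stringsAsFactors = FALSE)
  truth <- structure(list(objects = objects, params = p), class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' Acquisition metadata
#'
#' @param pixel_size um/px. @param frame_interval s.
#' @param stim_point (x, y) in um. @param stim_events data.frame with columns
#'   `frame` (0-based) and `duration_s`. @param channel_roles named character.
#' @return `acquisition_meta` object.
#' @export
acquisition_meta <- function(pixel_size, frame_interval, stim_point = NULL,
                             stim_events = NULL, channel_roles = NULL) {
  if (pixel_size <= 0) mp_stop("pixel_size must be positive")
  if (frame_interval <= 0) mp_stop("frame_interval must be positive")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 stim_point = stim_point, stim_events = stim_events,
                 channel_roles = channel_roles), class = "acquisition_meta")
}
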