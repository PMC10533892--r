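#' Simulation parameters for synthetic photostimulation movies
#'
#' Builds and validates the parameter set that defines a synthetic two-channel
#' recording: a field of capsule-shaped mitochondria imaged in a biosensor
#' channel (H2O2 probe, 488 nm excitation) and a photosensitizer channel
#' (561 nm), with a fixed spot-stimulation point and one or more 5-s
#' photostimulation pulses.
#'
#' Defaults encode the acquisition and response regime of the single-
#' mitochondrion photostimulation experiments the generator emulates:
#' 19.3 px/um optical sampling, 5-s frame cadence over 230 frames, a
#' baseline period followed by two stimulation pulses, an immediate ~65%
#' fractional biosensor rise at the stimulation point, a linear-with-cutoff
#' distance attenuation with microdomain-specific extinction distances
#' (12, 6 and 1 um for matrix, IMS and OMM probes), a plateau followed by
#' single-phase decay with per-pulse rate constants 0.54 and 0.085 F/F0 per
#' minute, photosensitizer photobleaching at each pulse, and transient
#' elongation of mitochondria close to the stimulation point.
#'
#' @param image_shape integer length-2, image height and width in pixels.
#' @param pixel_size pixel size in um/px (default 1/19.3).
#' @param frame_interval frame interval in seconds.
#' @param n_frames number of frames.
#' @param n_mitos number of mitochondria.
#' @param mito_length_range length-2 numeric, capsule end-to-end length range (um).
#' @param mito_width_range length-2 numeric, capsule width range (um).
#' @param motion_sigma per-frame Brownian step standard deviation (um/frame).
#' @param stim_point length-2 numeric, stimulation point (x, y) in um.
#' @param stim_frames integer vector of stimulation frame indices (0-based).
#' @param stim_duration_s duration of each stimulation pulse (s).
#' @param response_amplitude fractional biosensor rise at distance 0 (A0).
#' @param response_range named numeric, extinction distance d_max (um) per
#'   microdomain; the `microdomain` entry selects which applies.
#' @param microdomain which biosensor targeting is simulated:
#'   `"matrix"`, `"IMS"` or `"OMM"`.
#' @param plateau_duration post-rise plateau duration (s).
#' @param decay_rate decay rate constant(s) K in F/F0 per minute; recycled to
#'   one value per stimulation pulse (defaults 0.54 then 0.085).
#' @param bleach_fraction photosensitizer signal fraction lost per pulse at
#'   distance 0.
#' @param elongation_factor maximal major-axis stretch of near-spot
#'   mitochondria after a pulse.
#' @param elongation_duration duration of the transient elongation window (s).
#' @param baseline_biosensor,baseline_photosensitizer per-pixel signal
#'   densities (counts) inside a mitochondrion at baseline.
#' @param background_level camera offset / background level (counts).
#' @param noise_read_sigma Gaussian read-noise standard deviation (counts).
#' @param noise_shot logical, apply Poisson shot noise to the signal.
#' @param min_clearance minimal boundary-to-boundary clearance kept between
#'   mitochondria (um); placement and motion enforce it so the segmentation
#'   ground truth stays well defined.
#' @param rng_seed integer seed for reproducible simulation.
#'
#' @return An object of class `sim_params` (a validated list).
#' @export
#' @examples
#' p <- sim_params(n_mitos = 3, n_frames = 30, image_shape = c(128, 128))
#' p$response_amplitude
sim_params <- function(image_shape = c(300L, 300L),
                       pixel_size = 1 / 19.3,
                       frame_interval = 5,
                       n_frames = 230L,
                       n_mitos = 20L,
                       mito_length_range = c(0.8, 2),
                       mito_width_range = c(0.5, 0.8),
                       motion_sigma = 0.02,
                       stim_point = NULL,
                       stim_frames = c(24L, 120L),
                       stim_duration_s = 5,
                       response_amplitude = 0.65,
                       response_range = c(matrix = 12, IMS = 6, OMM = 1),
                       microdomain = c("matrix", "IMS", "OMM"),
                       plateau_duration = 60,
                       decay_rate = c(0.54, 0.085),
                       bleach_fraction = 0.6,
                       elongation_factor = 1.3,
                       elongation_duration = 120,
                       baseline_biosensor = 300,
                       baseline_photosensitizer = 300,
                       background_level = 100,
                       noise_read_sigma = 5,
                       noise_shot = TRUE,
                       min_clearance = 0.4,
                       rng_seed = 1L) {
  microdomain <- match.arg(microdomain)
  image_shape <- as.integer(image_shape)
  n_frames <- as.integer(n_frames)
  n_mitos <- as.integer(n_mitos)
  stim_frames <- as.integer(stim_frames)
  if (is.null(stim_point)) {
    # default: a point in the lower-left quadrant so distal distances exist
    fov <- image_shape * pixel_size
    stim_point <- c(0.25 * fov[2], 0.25 * fov[1])
  }
  p <- structure(list(
    image_shape = image_shape, pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = n_frames, n_mitos = n_mitos,
    mito_length_range = as.numeric(mito_length_range),
    mito_width_range = as.numeric(mito_width_range),
    motion_sigma = motion_sigma, stim_point = as.numeric(stim_point),
    stim_frames = stim_frames, stim_duration_s = stim_duration_s,
    response_amplitude = response_amplitude,
    response_range = response_range, microdomain = microdomain,
    plateau_duration = plateau_duration,
    decay_rate = rep_len(as.numeric(decay_rate), max(1L, length(stim_frames))),
    bleach_fraction = bleach_fraction,
    elongation_factor = elongation_factor,
    elongation_duration = elongation_duration,
    baseline_biosensor = baseline_biosensor,
    baseline_photosensitizer = baseline_photosensitizer,
    background_level = background_level,
    noise_read_sigma = noise_read_sigma, noise_shot = isTRUE(noise_shot),
    min_clearance = min_clearance, rng_seed = as.integer(rng_seed)
  ), class = "sim_params")
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (length(p$image_shape) != 2L || any(p$image_shape < 8L))
    mp_stop("image_shape must be two integers >= 8")
  if (p$pixel_size <= 0) mp_stop("pixel_size must be positive")
  if (p$frame_interval <= 0) mp_stop("frame_interval must be positive")
  if (p$n_frames < 1L) mp_stop("n_frames must be >= 1")
  if (p$n_mitos < 0L) mp_stop("n_mitos must be >= 0")
  rng_ok <- function(r) length(r) == 2L && all(r > 0) && r[1] <= r[2]
  if (!rng_ok(p$mito_length_range)) mp_stop("invalid mito_length_range")
  if (!rng_ok(p$mito_width_range)) mp_stop("invalid mito_width_range")
  if (p$motion_sigma < 0) mp_stop("motion_sigma must be >= 0")
  if (length(p$stim_frames) &&
      (any(p$stim_frames < 0L) || any(p$stim_frames >= p$n_frames)))
    mp_stop("stim_frames must lie within [0, n_frames)")
  if (p$response_amplitude < 0) mp_stop("response_amplitude must be >= 0")
  if (any(p$response_range <= 0)) mp_stop("response_range entries must be > 0")
  if (!p$microdomain %in% names(p$response_range))
    mp_stop("microdomain has no matching response_range entry")
  if (p$plateau_duration < 0) mp_stop("plateau_duration must be >= 0")
  if (any(p$decay_rate < 0)) mp_stop("decay_rate must be >= 0")
  if (p$bleach_fraction < 0 || p$bleach_fraction > 1)
    mp_stop("bleach_fraction must be in [0, 1]")
  if (p$elongation_factor < 1) mp_stop("elongation_factor must be >= 1")
  if (p$noise_read_sigma < 0) mp_stop("noise_read_sigma must be >= 0")
  p
}

#' Distance attenuation of the photostimulation response
#'
#' Linear-with-cutoff attenuation `A(d) = A0 * max(0, 1 - d/d_max)`: the
#' fractional biosensor rise decreases linearly with distance from the
#' stimulation point and is extinguished at `d_max`.
#'
#' @param d distance(s) from the stimulation point (um).
#' @param A0 fractional rise at distance zero.
#' @param d_max extinction distance (um).
#' @return numeric vector of fractional rises.
#' @export
response_attenuation <- function(d, A0, d_max) {
  if (d_max <= 0) mp_stop("d_max must be positive")
  A0 * pmax(0, 1 - d / d_max)
}
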