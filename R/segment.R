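# Per-frame preprocessing, threshold segmentation and region measurement.

#' Rolling-ball style background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' frame with a disk of the given radius (erosion then dilation) and
#' subtracts it. Structures smaller than the disk survive; any constant
#' offset is removed exactly. Output is clipped at zero.
#'
#' @param frame numeric matrix (one image).
#' @param radius disk radius in pixels (>= 1).
#' @return matrix of the same shape, >= 0.
#' @export
subtract_background <- function(frame, radius = 50) {
  if (radius < 1) mp_stop("radius must be >= 1")
  if (radius >= min(dim(frame))) mp_stop("radius larger than the image")
  opened <- disk_filter_cpp(disk_filter_cpp(frame, as.integer(radius), TRUE),
                            as.integer(radius), FALSE)
  pmax(frame - opened, 0)
}

#' Gaussian smoothing
#'
#' Separable Gaussian convolution with reflective boundaries; total intensity
#' of interior objects is conserved.
#'
#' @param frame numeric matrix. @param sigma kernel standard deviation (px).
#' @return smoothed matrix.
#' @export
smooth_frame <- function(frame, sigma = 2) {
  if (sigma <= 0) mp_stop("sigma must be positive")
  gaussian_blur_cpp(frame, sigma)
}

#' Otsu threshold
#'
#' Classic between-class-variance maximization on a 256-bin histogram.
#'
#' @param x numeric vector or matrix of intensities.
#' @return threshold value (same units as `x`).
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nb)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(bcv)]
}

#' Crofton perimeter of binary masks in a label image
#'
#' Boundary length by the 4-direction Crofton (Cauchy) formula: intercept
#' counts along rows, columns and both diagonals, weighted by line spacing.
#' Substantially less biased than raw pixel-edge counting; worst-case
#' anisotropic bias about 5% for very elongated shapes.
#'
#' @param mask logical matrix (one object), not touching the border handled
#'   by internal zero padding.
#' @return perimeter in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  nh <- sum(m[, -1] != m[, -nc])
  nv <- sum(m[-1, ] != m[-nr, ])
  nd1 <- sum(m[-1, -1] != m[-nr, -nc])
  nd2 <- sum(m[-1, -nc] != m[-nr, -1])
  (pi / 4) * (nh / 2 + nv / 2 + (nd1 / 2 + nd2 / 2) / sqrt(2))
}

#' Segmentation configuration
#'
#' @param channel channel used for mask generation (`"biosensor"` or
#'   `"photosensitizer"`).
#' @param background_radius rolling-ball radius (px).
#' @param sigma Gaussian smoothing sigma (px).
#' @param threshold `"otsu"` or a numeric threshold on the smoothed image.
#' @param min_area_um2 minimum object area kept (um^2).
#' @param refine `"halfmax"` re-thresholds each detected component at
#'   `halfmax_frac` of its own intensity maximum (the full-width-half-maximum
#'   boundary of an object sits on its true edge); `"none"` keeps the
#'   global-threshold mask. Refinement runs on the unsmoothed
#'   background-subtracted channel: the smoothed image is good for detection
#'   but its half-max contour is pulled inward wherever the boundary is
#'   convex (curvature bias of the order sigma^2 / radius).
#' @param halfmax_frac fraction of the per-object (robust) maximum used by
#'   the refinement.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(channel = "biosensor", background_radius = 50,
                                sigma = 2, threshold = "otsu",
                                min_area_um2 = 0.1,
                                refine = c("halfmax", "none"),
                                halfmax_frac = 0.5) {
  refine <- match.arg(refine)
  structure(list(channel = channel, background_radius = background_radius,
                 sigma = sigma, threshold = threshold,
                 min_area_um2 = min_area_um2, refine = refine,
                 halfmax_frac = halfmax_frac), class = "segmentation_config")
}

#' Segment one preprocessed frame
#'
#' Connected components (8-connectivity) above an intensity threshold,
#' followed by a minimum-area filter and optional per-object half-maximum
#' boundary refinement. Measurements are computed per region on the supplied
#' intensity channels and reported in physical units.
#'
#' @param frame preprocessed (background-subtracted, smoothed) matrix used
#'   for mask generation.
#' @param config a [segmentation_config()].
#' @param pixel_size um/px.
#' @param intensity_channels named list of matrices (background-subtracted,
#'   unsmoothed) from which per-region summed intensities are measured;
#'   defaults to the mask frame itself.
#' @return list with `labels` (integer matrix) and `measurements`
#'   (data.frame: label, area_um2, perimeter_um, major_um, minor_um, x_um,
#'   y_um, and one `sum_<channel>` column per intensity channel).
#' @export
segment_frame <- function(frame, config = segmentation_config(),
                          pixel_size = 1 / 19.3,
                          intensity_channels = NULL) {
  if (is.null(intensity_channels)) intensity_channels <- list(value = frame)
  thr <- if (identical(config$threshold, "otsu")) otsu_threshold(frame)
         else as.numeric(config$threshold)
  mask <- frame > thr
  labels <- label_components_cpp(mask)
  if (config$refine == "halfmax" && max(labels) > 0L) {
    # Local adaptive re-threshold. The global detection threshold can sit
    # well above an individual (dim) object's half-maximum, eroding its
    # component, so refinement re-thresholds the raw image at half the
    # object's own robust maximum inside an expanded bounding box and keeps
    # the raw components overlapping the detection.
    rimg <- if (config$channel %in% names(intensity_channels))
      intensity_channels[[config$channel]] else frame
    nr <- nrow(frame); nc <- ncol(frame)
    refined <- matrix(0L, nr, nc)
    pad <- 6L
    for (l in seq_len(max(labels))) {
      idx <- which(labels == l, arr.ind = TRUE)
      # robust per-object maximum: insensitive to single hot pixels
      tl <- config$halfmax_frac *
        as.numeric(stats::quantile(rimg[labels == l], 0.98))
      r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nr, max(idx[, 1]) + pad)
      c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(nc, max(idx[, 2]) + pad)
      if (tl <= 0) {
        refined[idx] <- l
        next
      }
      comp <- label_components_cpp(rimg[r0:r1, c0:c1, drop = FALSE] >= tl)
      hit <- comp[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)]
      keep <- unique(hit[hit > 0L])
      if (!length(keep)) {
        refined[idx] <- l
      } else {
        sub <- refined[r0:r1, c0:c1, drop = FALSE]
        sub[comp %in% keep] <- l
        refined[r0:r1, c0:c1] <- sub
      }
    }
    # refinement can split or regrow regions; relabel to keep components atomic
    labels <- label_components_cpp(refined > 0L)
  }
  measurements <- measure_regions(labels, intensity_channels, pixel_size)
  min_px <- config$min_area_um2 / pixel_size^2
  keep <- measurements$area_um2 / pixel_size^2 >= min_px
  measurements <- measurements[keep, , drop = FALSE]
  labels[!(labels %in% measurements$label)] <- 0L
  rownames(measurements) <- NULL
  list(labels = labels, measurements = measurements)
}

#' Measure labeled regions
#'
#' Area from pixel counts, centroid from binary moments, major/minor axis
#' lengths from the second-moment ellipse (4 sqrt(eigenvalue) convention),
#' perimeter by [crofton_perimeter()], summed intensity per channel.
#' Lengths in um, areas in um^2, using the top-left-pixel-centre um
#' coordinate frame.
#'
#' @param labels integer label matrix (0 = background).
#' @param intensity_channels named list of matrices.
#' @param pixel_size um/px.
#' @return data.frame, one row per label.
#' @export
measure_regions <- function(labels, intensity_channels, pixel_size) {
  n <- max(labels)
  sum_cols <- paste0("sum_", names(intensity_channels))
  empty <- as.data.frame(c(
    list(label = integer(), area_um2 = numeric(), perimeter_um = numeric(),
         major_um = numeric(), minor_um = numeric(),
         x_um = numeric(), y_um = numeric()),
    setNames(rep(list(numeric()), length(sum_cols)), sum_cols)))
  if (n == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  ii <- (idx - 1L) %% nrow(labels)       # 0-based row -> y
  jj <- (idx - 1L) %/% nrow(labels)      # 0-based col -> x
  area_px <- tabulate(lab, n)
  cx <- tapply(jj, lab, mean)
  cy <- tapply(ii, lab, mean)
  # central second moments of the binary mask (+1/12 pixel-integration term)
  mu20 <- tapply(seq_along(lab), lab, function(k) mean((jj[k] - mean(jj[k]))^2)) + 1 / 12
  mu02 <- tapply(seq_along(lab), lab, function(k) mean((ii[k] - mean(ii[k]))^2)) + 1 / 12
  mu11 <- tapply(seq_along(lab), lab, function(k)
    mean((jj[k] - mean(jj[k])) * (ii[k] - mean(ii[k]))))
  common <- (mu20 + mu02) / 2
  diff2 <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  major <- 4 * sqrt(pmax(common + diff2, 0))
  minor <- 4 * sqrt(pmax(common - diff2, 0))
  perim <- vapply(seq_len(n), function(l) crofton_perimeter(labels == l), 0.0)
  out <- data.frame(
    label = seq_len(n), area_um2 = area_px * pixel_size^2,
    perimeter_um = perim * pixel_size,
    major_um = major * pixel_size, minor_um = minor * pixel_size,
    x_um = as.numeric(cx) * pixel_size, y_um = as.numeric(cy) * pixel_size)
  for (k in seq_along(intensity_channels)) {
    v <- intensity_channels[[k]][idx]
    out[[sum_cols[k]]] <- as.numeric(tapply(v, lab, sum))
  }
  out
}

#' Detect single-frame intensity artifacts
#'
#' Flags frames whose whole-image median deviates from the median of their
#' neighbours by more than `n_mad` median absolute deviations of the
#' frame-to-frame differences. At most one frame per recording is flagged
#' (the worst offender), mirroring how rare technical artifacts are handled.
#'
#' @param movie a `movie_stack`. @param channel channel name. @param n_mad
#'   threshold in MAD units (default 5).
#' @return integer vector of 0-based frame indices (length 0 or 1).
#' @export
detect_artifact_frames <- function(movie, channel = "biosensor", n_mad = 5) {
  d <- movie$data[, , , channel, drop = FALSE]
  nf <- dim(d)[3]
  if (nf < 3L) return(integer())
  med <- vapply(seq_len(nf), function(f) stats::median(d[, , f, 1]), 0.0)
  neigh <- vapply(seq_len(nf), function(f) {
    k <- setdiff(c(f - 1L, f + 1L), c(0L, nf + 1L))
    mean(med[k])
  }, 0.0)
  dev <- abs(med - neigh)
  # robust frame-to-frame scale, floored at 0.1% of the median level so a
  # lone spike in an otherwise constant recording is still detectable
  s <- max(stats::mad(diff(med)), 1e-3 * abs(stats::median(med)),
           .Machine$double.eps)
  cand <- which(dev > n_mad * s)
  if (!length(cand)) return(integer())
  cand[which.max(dev[cand])] - 1L
}

#' Segment a whole movie
#'
#' Applies background subtraction, smoothing and [segment_frame()] to each
#' frame. Summed intensities are measured on the background-subtracted
#' (unsmoothed) images of all channels. Frames flagged by
#' [detect_artifact_frames()] are dropped (at most one), leaving a gap for
#' the tracker to bridge.
#'
#' @param movie a `movie_stack`.
#' @param config a [segmentation_config()].
#' @param drop_artifacts logical, apply single-frame artifact removal.
#' @return list of per-frame data.frames (NULL for dropped frames), each with
#'   a `frame` column (0-based), plus attribute `dropped_frames`.
#' @export
segment_movie <- function(movie, config = segmentation_config(),
                          drop_artifacts = TRUE) {
  d <- movie$data
  nf <- dim(d)[3]
  ps <- movie$meta$pixel_size
  channels <- dimnames(d)[[4]]
  dropped <- if (drop_artifacts)
    detect_artifact_frames(movie, channel = config$channel) else integer()
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    if ((f - 1L) %in% dropped) next
    chans <- lapply(channels, function(ch)
      subtract_background(d[, , f, ch], config$background_radius))
    names(chans) <- channels
    sm <- smooth_frame(chans[[config$channel]], config$sigma)
    seg <- segment_frame(sm, config, pixel_size = ps,
                         intensity_channels = chans)
    m <- seg$measurements
    if (nrow(m)) m <- cbind(frame = f - 1L, m)
    out[[f]] <- m
  }
  attr(out, "dropped_frames") <- dropped
  out
}
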