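# Minimal multi-page TIFF I/O: baseline TIFF, little-endian, 16-bit unsigned
# grayscale, uncompressed, one strip per page. This covers exactly the files
# the simulator writes; foreign TIFF variants are rejected with a clear error.

tiff_types <- c(SHORT = 3L, LONG = 4L)

#' Write a movie as a multi-page 16-bit TIFF with a JSON metadata sidecar
#'
#' Pages are frame-major and channel-interleaved: page `(f-1)*C + c` holds
#' frame `f`, channel `c`. Intensities are rounded and clipped to the
#' unsigned 16-bit range. Acquisition metadata (pixel size, frame interval,
#' stimulation point and events, channel roles) goes into a JSON sidecar next
#' to the TIFF (same path with extension `.json`).
#'
#' @param movie a `movie_stack` (see [simulate_movie()]).
#' @param path output TIFF path.
#' @return invisibly, the sidecar path.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- movie$data
  h <- dim(d)[1]; w <- dim(d)[2]; nf <- dim(d)[3]; nc <- dim(d)[4]
  n_pages <- nf * nc
  page_bytes <- h * w * 2L
  ifd_size <- 2L + 9L * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + n_pages * page_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_start, con, size = 4, endian = "little")

  for (f in seq_len(nf)) for (ch in seq_len(nc)) {
    page <- t(d[, , f, ch])  # row-major pixel order
    v <- as.integer(pmin(pmax(round(page), 0), 65535))
    writeBin(v, con, size = 2, endian = "little")
  }

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == tiff_types[["SHORT"]]) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (pg in seq_len(n_pages)) {
    writeBin(9L, con, size = 2, endian = "little")
    entry(256, 4, 1, w)                                   # ImageWidth
    entry(257, 4, 1, h)                                   # ImageLength
    entry(258, 3, 1, 16)                                  # BitsPerSample
    entry(259, 3, 1, 1)                                   # Compression: none
    entry(262, 3, 1, 1)                                   # Photometric: minisblack
    entry(273, 4, 1, data_start + (pg - 1L) * page_bytes) # StripOffsets
    entry(278, 4, 1, h)                                   # RowsPerStrip
    entry(279, 4, 1, page_bytes)                          # StripByteCounts
    entry(339, 3, 1, 1)                                   # SampleFormat: uint
    nxt <- if (pg < n_pages) ifd_start + pg * ifd_size else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }

  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- movie$meta
  jsonlite::write_json(list(
    image_shape = c(h, w), n_frames = nf, n_channels = nc,
    channel_names = dimnames(d)[[4]],
    pixel_size = meta$pixel_size, frame_interval = meta$frame_interval,
    stim_point = meta$stim_point,
    stim_events = meta$stim_events,
    channel_roles = as.list(meta$channel_roles)
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

read_uint <- function(raw, off, size) {
  # off is 0-based; returns non-negative integer value
  b <- as.integer(raw[off + seq_len(size)])
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path; the JSON sidecar is expected at the same path with
#'   extension `.json` (or pass `meta_path`).
#' @param meta_path optional explicit sidecar path.
#' @return a `movie_stack`.
#' @export
read_movie_tiff <- function(path, meta_path = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  if (rawToChar(raw[1:2]) != "II" || read_uint(raw, 2, 2) != 42L)
    mp_stop("not a little-endian TIFF file")
  ifd_off <- read_uint(raw, 4, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- read_uint(raw, ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- read_uint(raw, base, 2)
      type <- read_uint(raw, base + 2, 2)
      val <- if (type == 3) read_uint(raw, base + 8, 2) else read_uint(raw, base + 8, 4)
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) mp_stop("unsupported TIFF: missing tags")
    if (!is.null(tags[["258"]]) && tags[["258"]] != 16)
      mp_stop("unsupported TIFF: only 16-bit samples are supported")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      mp_stop("unsupported TIFF: compressed data not supported")
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- read_uint(raw, ifd_off + 2 + n_entries * 12, 4)
  }
  if (!length(pages)) mp_stop("TIFF contains no pages")

  sidecar <- if (is.null(meta_path))
    paste0(tools::file_path_sans_ext(path), ".json") else meta_path
  if (!file.exists(sidecar)) mp_stop("metadata sidecar not found: ", sidecar)
  meta_json <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  nf <- meta_json$n_frames; ncn <- meta_json$n_channels
  if (nf * ncn != length(pages))
    mp_stop("sidecar frame/channel counts do not match TIFF page count")

  w <- pages[[1]][["256"]]; h <- pages[[1]][["257"]]
  data <- array(0, dim = c(h, w, nf, ncn),
                dimnames = list(NULL, NULL, NULL, meta_json$channel_names))
  for (pg in seq_along(pages)) {
    off <- pages[[pg]][["273"]]
    nb <- pages[[pg]][["279"]]
    vals <- readBin(raw[off + seq_len(nb)], "integer", n = nb / 2, size = 2,
                    signed = FALSE, endian = "little")
    f <- ((pg - 1L) %/% ncn) + 1L
    ch <- ((pg - 1L) %% ncn) + 1L
    data[, , f, ch] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  }
  se <- meta_json$stim_events
  if (!is.null(se) && !is.data.frame(se)) se <- as.data.frame(se)
  meta <- acquisition_meta(
    pixel_size = meta_json$pixel_size, frame_interval = meta_json$frame_interval,
    stim_point = unlist(meta_json$stim_point), stim_events = se,
    channel_roles = unlist(meta_json$channel_roles))
  structure(list(data = data, meta = meta), class = "movie_stack")
}
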