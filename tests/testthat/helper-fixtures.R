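# Shared fixture builders (code-generated; nothing is stored on disk).

# Small noiseless movie used by segmentation/tracking/trace tests.
noiseless_params <- function(n_mitos = 4L, n_frames = 12L, seed = 7L,
                             stim_frames = 4L, ...) {
  sim_params(image_shape = c(128L, 128L), n_frames = n_frames,
             n_mitos = n_mitos, mito_length_range = c(0.8, 1.4),
             stim_frames = stim_frames, plateau_duration = 30,
             noise_shot = FALSE, noise_read_sigma = 0, rng_seed = seed, ...)
}

# Match each segmented/tracked row to the nearest ground-truth object of the
# same frame; returns the merged data.frame with relative area error.
match_to_truth <- function(tracked, truth) {
  out <- NULL
  for (f in unique(tracked$frame)) {
    s <- tracked[tracked$frame == f, , drop = FALSE]
    t0 <- truth[truth$frame == f, , drop = FALSE]
    j <- vapply(seq_len(nrow(s)), function(i)
      which.min((t0$x_um - s$x_um[i])^2 + (t0$y_um - s$y_um[i])^2), 0L)
    out <- rbind(out, data.frame(
      frame = f, track_id = s$track_id, true_id = t0$true_id[j],
      area_err = (s$area_um2 - t0$area_um2[j]) / t0$area_um2[j],
      dist_true = t0$dist_um[j]))
  }
  out
}

# Majority-vote identity per track; fraction of rows agreeing with it.
link_accuracy <- function(pairs) {
  maj <- tapply(pairs$true_id, pairs$track_id,
                function(v) as.integer(names(which.max(table(v)))))
  mean(pairs$true_id == maj[as.character(pairs$track_id)])
}

# Binary disk image (for morphometry oracles).
disk_image <- function(r, pad = 5L, amplitude = 100) {
  n <- 2L * (r + pad) + 1L
  cx <- r + pad
  img <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - 1 - cx)^2 + (j - 1 - cx)^2 <= r^2) img[i, j] <- amplitude
  img
}
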