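# Frame-to-frame identity linking by greedy mutual nearest neighbours.

#' Link per-frame measurements into tracks
#'
#' Greedy mutual-nearest-centroid assignment between the active track heads
#' and the detections of each frame, gated at `max_disp`. A track head whose
#' object was missed keeps competing for up to `max_gap` frames, with its
#' position extrapolated linearly from its last two points (gap bridging);
#' unmatched detections start new tracks. Every measurement row ends up in
#' exactly one track.
#'
#' @param measurements list of per-frame data.frames as produced by
#'   [segment_movie()] (each with `frame`, `x_um`, `y_um`, ... columns);
#'   NULL entries are treated as dropped frames (a gap for all tracks).
#' @param max_disp maximum linking displacement (um) per frame step.
#' @param max_gap maximum number of consecutive missed frames bridged.
#' @param frame_interval seconds per frame, used for the `time_s` column.
#' @return data.frame of all measurements with `track_id` and `time_s`
#'   prepended, ordered by track then frame.
#' @export
link_tracks <- function(measurements, max_disp = 2, max_gap = 2,
                        frame_interval = 5) {
  frames <- Filter(function(m) !is.null(m) && nrow(m) > 0, measurements)
  if (!length(frames)) {
    return(data.frame(track_id = integer(), frame = integer(),
                      time_s = numeric()))
  }
  tracks <- list()   # each: id, rows (list of df rows), last_frame, pos, vel
  next_id <- 1L
  active <- integer()  # indices into tracks

  for (m in frames) {
    f <- m$frame[1]
    det <- cbind(m$x_um, m$y_um)
    nd <- nrow(det)
    assigned_det <- rep(FALSE, nd)
    if (length(active)) {
      # drop heads that exceeded the gap
      ages <- vapply(tracks[active], function(tr) f - tr$last_frame, 0)
      active <- active[ages <= max_gap + 1L]
    }
    if (length(active) && nd > 0) {
      pred <- t(vapply(tracks[active], function(tr) {
        dt <- f - tr$last_frame
        tr$pos + tr$vel * dt
      }, numeric(2)))
      dm <- sqrt(outer(pred[, 1], det[, 1], "-")^2 +
                 outer(pred[, 2], det[, 2], "-")^2)
      nt <- length(active)
      best_det <- apply(dm, 1, which.min)
      best_trk <- apply(dm, 2, which.min)
      for (a in seq_len(nt)) {
        b <- best_det[a]
        if (best_trk[b] == a && dm[a, b] <= max_disp) {
          k <- active[a]
          dt <- f - tracks[[k]]$last_frame
          newpos <- det[b, ]
          tracks[[k]]$vel <- (newpos - tracks[[k]]$pos) / dt
          tracks[[k]]$pos <- newpos
          tracks[[k]]$last_frame <- f
          tracks[[k]]$rows[[length(tracks[[k]]$rows) + 1L]] <- m[b, , drop = FALSE]
          assigned_det[b] <- TRUE
        }
      }
    }
    for (b in which(!assigned_det)) {
      tracks[[next_id]] <- list(id = next_id, rows = list(m[b, , drop = FALSE]),
                                last_frame = f, pos = det[b, ], vel = c(0, 0))
      active <- c(active, next_id)
      next_id <- next_id + 1L
    }
  }

  out <- do.call(rbind, lapply(tracks, function(tr) {
    df <- do.call(rbind, tr$rows)
    cbind(track_id = tr$id, time_s = df$frame * frame_interval, df)
  }))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
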