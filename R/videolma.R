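## Home-cage locomotor activity from greyscale video by frame differencing.

#' Changed-pixel count between two frames
#'
#' Counts pixels whose grey level changed by at least `grey_delta_min`
#' (inclusive) between consecutive frames; the per-pixel threshold limits
#' the effect of video compression noise.
#'
#' @param prev,cur greyscale frames (integer/numeric matrices of identical
#'   shape, grey levels 0-255).
#' @param grey_delta_min minimum per-pixel grey-level change (default 10).
#' @param frame_min_pixels optional frame-level floor (default 0, off):
#'   counts below it are reported as 0, the alternative reading of the
#'   compression threshold.
#' @return integer changed-pixel count.
#' @export
frame_motion <- function(prev, cur, grey_delta_min = 10,
                         frame_min_pixels = 0) {
  abort_if(!identical(dim(prev), dim(cur)), "frames must have the same shape")
  n <- sum(abs(as.numeric(cur) - as.numeric(prev)) >= grey_delta_min)
  if (n < frame_min_pixels) 0L else n
}

#' Motion trace of a frame sequence
#'
#' Per-frame changed-pixel counts (first frame 0 by convention) with
#' photoperiod annotation and per-period relative distance (the sum of
#' counts over each period's frames) in arbitrary units.
#'
#' @param frames list of greyscale frames.
#' @param schedule a [photoperiod_schedule()].
#' @param frame_rate frames per second (default 25).
#' @param start_clock_time clock time (hours) of the first frame.
#' @param grey_delta_min per-pixel threshold, see [frame_motion()].
#' @return object of class `motion_trace`: list with `counts`,
#'   `photoperiod` (per frame), `frame_rate`, and `period_distance`
#'   (named numeric, LIGHT/DARK sums).
#' @export
motion_trace <- function(frames, schedule = photoperiod_schedule(),
                         frame_rate = 25, start_clock_time = 6,
                         grey_delta_min = 10) {
  abort_if(length(frames) < 2, "need at least two frames")
  n <- length(frames)
  counts <- integer(n)
  for (t in 2:n) {
    counts[t] <- frame_motion(frames[[t - 1]], frames[[t]], grey_delta_min)
  }
  clock <- (start_clock_time + (seq_len(n) - 1) / frame_rate / 3600) %% 24
  phase <- photoperiod_of(clock, schedule)
  dist <- c(LIGHT = sum(counts[phase == "LIGHT"]),
            DARK = sum(counts[phase == "DARK"]))
  structure(list(counts = counts, photoperiod = phase,
                 frame_rate = frame_rate, period_distance = dist),
            class = "motion_trace")
}
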