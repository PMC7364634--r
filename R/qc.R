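## Quality control: clipping and flat-line detection per epoch, the >5%
## week-exclusion rule, and the late-stage low-amplitude reliability flag.

#' Detect signal clipping in an epoch
#'
#' An epoch is clipped when at least `min_fraction` of its samples sit
#' within `rail_fraction` of the week's amplitude rail, in contiguous runs
#' of at least `run_min` samples (isolated large samples are physiology,
#' sustained saturation is not).
#'
#' @param x epoch EEG sample block.
#' @param rail week-level amplitude rail (uV): the maximum absolute value
#'   observed over the animal-week.
#' @param rail_fraction fraction of the rail that counts as saturated
#'   (default 0.98).
#' @param run_min minimum saturated run length in samples (default 5).
#' @param min_fraction minimum fraction of saturated samples (default 0.01).
#' @return logical.
#' @export
detect_clipping <- function(x, rail, rail_fraction = 0.98, run_min = 5,
                            min_fraction = 0.01) {
  if (rail <= 0) return(FALSE)
  sat <- abs(x) >= rail_fraction * rail
  if (!any(sat)) return(FALSE)
  r <- rle(sat)
  good <- sum(r$lengths[r$values & r$lengths >= run_min])
  good / length(x) >= min_fraction
}

#' Detect a flat-line epoch
#'
#' True when any contiguous window of `run_seconds` has variance below
#' `var_floor`.
#'
#' @param x epoch EEG sample block.
#' @param fs sampling rate (Hz).
#' @param var_floor variance floor (uV^2), default 1e-3.
#' @param run_seconds window length (s), default 2.
#' @return logical.
#' @export
detect_flatline <- function(x, fs, var_floor = 1e-3, run_seconds = 2) {
  w <- min(as.integer(round(run_seconds * fs)), length(x))
  if (w < 2) return(stats::var(x) < var_floor)
  step <- max(1L, w %/% 4L)
  starts <- unique(c(seq(1L, length(x) - w + 1L, by = step),
                     length(x) - w + 1L))
  for (s in starts) {
    if (stats::var(x[s:(s + w - 1L)]) < var_floor) return(TRUE)
  }
  FALSE
}

#' Per-epoch artefact flags for a recording
#'
#' Runs the clipping and flat-line detectors on every epoch, using the
#' whole recording's maximum absolute amplitude as the rail context.
#'
#' @param recording a `recording`.
#' @param epoch_seconds epoch length (s).
#' @param rail_fraction,run_min,min_fraction see [detect_clipping()].
#' @param var_floor,run_seconds see [detect_flatline()].
#' @return data.frame with `epoch_index`, `flag`, `reason` ("", "CLIP",
#'   "FLAT"; flat takes precedence).
#' @export
qc_epoch_flags <- function(recording, epoch_seconds = 10,
                           rail_fraction = 0.98, run_min = 5,
                           min_fraction = 0.01, var_floor = 1e-3,
                           run_seconds = 2) {
  ep <- epoch_split(recording, epoch_seconds)
  rail <- if (ep$n_epochs) max(abs(ep$eeg)) else 0
  flag <- logical(ep$n_epochs)
  reason <- character(ep$n_epochs)
  for (i in seq_len(ep$n_epochs)) {
    x <- ep$eeg[, i]
    if (detect_flatline(x, ep$fs, var_floor, run_seconds)) {
      flag[i] <- TRUE; reason[i] <- "FLAT"
    } else if (detect_clipping(x, rail, rail_fraction, run_min,
                               min_fraction)) {
      flag[i] <- TRUE; reason[i] <- "CLIP"
    }
  }
  data.frame(epoch_index = seq_len(ep$n_epochs), flag = flag,
             reason = reason, stringsAsFactors = FALSE)
}

#' Apply the week-level artefact exclusion rule
#'
#' A week of data is excluded when artefacts exceed 5% of its epochs —
#' strictly greater, so exactly 5% is retained.
#'
#' @param flags logical vector of per-epoch artefact flags for one
#'   animal-week (or a data.frame from [qc_epoch_flags()]).
#' @return object of class `artefact_report`: list with `epoch_flags`,
#'   `artefact_fraction`, `week_excluded`.
#' @export
apply_week_exclusion <- function(flags) {
  if (is.data.frame(flags)) flags <- flags$flag
  abort_if(length(flags) == 0, "need at least one epoch")
  frac <- mean(flags)
  structure(list(epoch_flags = flags, artefact_fraction = frac,
                 week_excluded = frac > 0.05),
            class = "artefact_report")
}

#' Flag weeks whose EEG amplitude is too low for reliable staging
#'
#' Progressive amplitude loss can shrink the EEG to the point where
#' period-amplitude scoring is no longer trustworthy. A week is flagged
#' when its median total power falls below `floor_fraction` of the
#' animal's first-week median; flagged weeks are dropped from
#' staging-dependent outcomes but retained for raw power reporting.
#'
#' @param weekly_total_power named numeric vector (or list) of per-week
#'   median total power, in age order; the first element is the baseline.
#' @param floor_fraction fraction of baseline below which staging is
#'   unreliable (default 0.2).
#' @return logical vector, one flag per week (baseline always `FALSE`).
#' @export
low_amplitude_flag <- function(weekly_total_power, floor_fraction = 0.2) {
  p <- as.numeric(weekly_total_power)
  abort_if(length(p) == 0, "no weekly power values supplied")
  if (!is.finite(p[1]) || p[1] <= 0) {
    warning("no usable baseline week; low-amplitude flag indeterminate")
    return(rep(NA, length(p)))
  }
  p < floor_fraction * p[1]
}
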