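## Signal conditioning and per-epoch feature extraction: zero-phase
## bandpass, 10-s epoching with photoperiod annotation, EMG RMS, Welch band
## power, and period-amplitude (half-wave) features.

#' EEG analysis band definitions
#'
#' The study bands with half-open intervals (lo, hi]: delta (0.1, 4],
#' theta (5.1, 9], alpha (9.1, 12], beta (12, 20] and total (0.1, 30].
#' The gaps at 4-5.1 Hz and 9-9.1 Hz belong to no named band.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "total"),
             lo = c(0.1, 5.1, 9.1, 12, 0.1),
             hi = c(4, 9, 12, 20, 30),
             stringsAsFactors = FALSE)
}

#' Construct a recording object
#'
#' A single differential EEG channel and an EMG channel sampled at `fs`,
#' with photoperiod schedule and animal metadata.
#'
#' @param eeg,emg numeric sample series of equal length (EEG in uV, EMG in
#'   arbitrary units).
#' @param fs sampling rate (Hz).
#' @param start_clock_time clock time (hours) of the first sample.
#' @param schedule a [photoperiod_schedule()].
#' @param animal_id,group,age_week metadata.
#' @return object of class `recording`.
#' @export
new_recording <- function(eeg, emg, fs, start_clock_time = 6,
                          schedule = photoperiod_schedule(),
                          animal_id = "a1", group = "WT", age_week = 20) {
  abort_if(length(eeg) != length(emg),
           "eeg and emg must have the same length")
  abort_if(fs <= 0, "fs must be positive")
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg), fs = fs,
                 start_clock_time = start_clock_time, schedule = schedule,
                 animal_id = animal_id, group = group, age_week = age_week),
            class = "recording")
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth applied forwards and backwards
#' (`signal::filtfilt`), so the output has no group delay and half-wave
#' timing is preserved. If `hi` exceeds 95% of Nyquist it is capped with a
#' warning (the acquisition band of a high-rate system cannot be honoured at
#' a reduced working rate).
#'
#' @param x numeric sample series.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz), `0 < lo < hi`.
#' @return filtered series, same length as `x`.
#' @export
bandpass <- function(x, fs, lo, hi) {
  abort_if(lo <= 0 || lo >= hi, "need 0 < lo < hi")
  nyq <- fs / 2
  cap <- 0.95 * nyq
  if (hi > cap) {
    warning(sprintf("upper edge %.5g Hz capped at %.5g Hz (0.95 x Nyquist)",
                    hi, cap))
    hi <- cap
  }
  bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Split a recording into annotated epochs
#'
#' Consecutive non-overlapping blocks of `epoch_seconds`; a trailing partial
#' epoch is dropped. Each epoch is annotated with its start clock time and
#' photoperiod.
#'
#' @param recording a `recording`.
#' @param epoch_seconds epoch length (s), default 10.
#' @return list with `eeg`, `emg` (samples x epochs matrices), `n_epochs`,
#'   `samples_per_epoch`, `clock_time` and `photoperiod` (per epoch),
#'   `epoch_seconds`, `fs`.
#' @export
epoch_split <- function(recording, epoch_seconds = 10) {
  abort_if(epoch_seconds <= 0, "epoch_seconds must be positive")
  nsamp <- as.integer(round(epoch_seconds * recording$fs))
  n_ep <- length(recording$eeg) %/% nsamp
  if (n_ep == 0L) {
    warning("recording shorter than one epoch; returning no epochs")
    return(list(eeg = matrix(numeric(0), nsamp, 0),
                emg = matrix(numeric(0), nsamp, 0),
                n_epochs = 0L, samples_per_epoch = nsamp,
                clock_time = numeric(0), photoperiod = character(0),
                epoch_seconds = epoch_seconds, fs = recording$fs))
  }
  keep <- seq_len(n_ep * nsamp)
  clock <- (recording$start_clock_time +
              (seq_len(n_ep) - 1) * epoch_seconds / 3600) %% 24
  list(eeg = matrix(recording$eeg[keep], nrow = nsamp),
       emg = matrix(recording$emg[keep], nrow = nsamp),
       n_epochs = n_ep, samples_per_epoch = nsamp,
       clock_time = clock,
       photoperiod = photoperiod_of(clock, recording$schedule),
       epoch_seconds = epoch_seconds, fs = recording$fs)
}

#' Root-mean-square of an EMG epoch
#'
#' @param x numeric sample block (non-empty).
#' @return sqrt(mean(x^2)).
#' @export
emg_rms <- function(x) {
  abort_if(length(x) == 0, "empty sample block")
  sqrt(mean(x^2))
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed segments with 50%
#' overlap, one-sided density scaling, segment means removed. With 2-s
#' segments the frequency resolution is 0.5 Hz, adequate for the 0.1-30 Hz
#' analysis range at epoch scale.
#'
#' @param x numeric sample series.
#' @param fs sampling rate (Hz).
#' @param seg_seconds segment length (s), default 2.
#' @param overlap fractional overlap, default 0.5.
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_seconds = 2, overlap = 0.5) {
  L <- min(as.integer(round(seg_seconds * fs)), length(x))
  abort_if(L < 8, "signal too short for spectral estimation")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  u <- sum(w^2)
  nfreq <- L %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nfreq] <- 1
  list(freq = seq(0, nfreq - 1) * fs / L, psd = psd * dbl)
}

#' Band power of an epoch
#'
#' Integrates the Welch PSD over the half-open band (lo, hi].
#'
#' @param x epoch sample block.
#' @param fs sampling rate (Hz).
#' @param band one row of [band_definitions()] (or any list with `lo`, `hi`).
#' @param psd optional precomputed [welch_psd()] result (re-used across
#'   bands for speed).
#' @return power in uV^2.
#' @export
band_power <- function(x, fs, band, psd = NULL) {
  abort_if(band$hi >= fs / 2, "band extends beyond Nyquist")
  if (is.null(psd)) psd <- welch_psd(x, fs)
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq > band$lo & psd$freq <= band$hi
  sum(psd$psd[sel]) * df
}

#' Period-amplitude (half-wave) features of an epoch
#'
#' The filtered, mean-centred signal is cut at its baseline (zero)
#' crossings; each half-wave between consecutive crossings carries an
#' equivalent frequency `f = 1 / (2 x duration)` and its peak absolute
#' amplitude. Counts and mean peak amplitudes are accumulated per band by
#' equivalent frequency; half-waves shorter than 1/(2 x 30 Hz) (sample-noise
#' crossings above the 30 Hz analysis ceiling) and half-waves falling in no
#' band are discarded.
#'
#' A crossing sits between samples `i` and `i+1` when their centred values
#' have strictly opposite signs; a half-wave spans the samples after one
#' crossing up to and including the next, with duration (in samples) the
#' index difference between crossings.
#'
#' @param x epoch sample block (already bandpassed to the analysis range).
#' @param fs sampling rate (Hz).
#' @param bands data.frame of band definitions (default the four named bands,
#'   excluding total).
#' @param min_freq_ceiling highest admissible equivalent frequency (Hz).
#' @return list with `incidence` and `amplitude`, both named by band
#'   (amplitude is `NA` where the count is 0).
#' @export
halfwave_features <- function(x, fs,
                              bands = subset(band_definitions(),
                                             name != "total"),
                              min_freq_ceiling = 30) {
  abort_if(fs < 2 * max(bands$hi),
           "sampling rate too low to resolve the requested bands")
  s <- x - mean(x)
  n <- length(s)
  inc <- stats::setNames(rep(0, nrow(bands)), bands$name)
  amp_sum <- inc
  if (n >= 2) {
    cross <- which(s[-n] * s[-1] < 0)     # crossing between i and i+1
    if (length(cross) >= 2) {
      start <- cross[-length(cross)]
      end <- cross[-1]
      dur <- (end - start) / fs
      keep <- dur >= 1 / (2 * min_freq_ceiling)
      start <- start[keep]; end <- end[keep]; dur <- dur[keep]
      if (length(dur)) {
        f <- 1 / (2 * dur)
        peak <- vapply(seq_along(start), function(k) {
          max(abs(s[(start[k] + 1L):end[k]]))
        }, numeric(1))
        for (b in seq_len(nrow(bands))) {
          sel <- f > bands$lo[b] & f <= bands$hi[b]
          inc[b] <- sum(sel)
          if (any(sel)) amp_sum[b] <- sum(peak[sel])
        }
      }
    }
  }
  amp <- ifelse(inc > 0, amp_sum / inc, NA_real_)
  names(amp) <- bands$name
  list(incidence = inc, amplitude = amp)
}

#' Extract per-epoch features from a recording
#'
#' Conditions the EEG (zero-phase 0.5-30 Hz working band by default, or up
#' to what the sampling rate allows), splits into epochs, and computes the
#' full feature vector per epoch: half-wave incidence and amplitude per
#' band, Welch band powers, total power and EMG RMS. The artefact flag is
#' initialised `FALSE`; quality control sets it later.
#'
#' @param recording a `recording`.
#' @param bands band definitions (default [band_definitions()]).
#' @param epoch_seconds epoch length (s).
#' @param condition if `TRUE`, bandpass the EEG to the analysis range
#'   before feature extraction.
#' @return data.frame, one row per epoch: `epoch_index`, `clock_time`,
#'   `photoperiod`, `hw_count_*`, `hw_amp_*`, `power_*`, `total_power`,
#'   `emg_rms`, `artefact`.
#' @export
extract_features <- function(recording, bands = band_definitions(),
                             epoch_seconds = 10, condition = TRUE) {
  named <- subset(bands, name != "total")
  total <- subset(bands, name == "total")
  abort_if(nrow(total) != 1, "bands must include a `total` definition")
  eeg <- recording$eeg
  if (condition && length(eeg)) {
    eeg <- bandpass(eeg, recording$fs, 0.5, min(30, 0.94 * recording$fs / 2))
  }
  rec <- recording
  rec$eeg <- eeg
  ep <- epoch_split(rec, epoch_seconds)
  n <- ep$n_epochs
  hw_count <- matrix(0, n, nrow(named),
                     dimnames = list(NULL, named$name))
  hw_amp <- matrix(NA_real_, n, nrow(named),
                   dimnames = list(NULL, named$name))
  pw <- matrix(0, n, nrow(named), dimnames = list(NULL, named$name))
  total_power <- numeric(n)
  rms <- numeric(n)
  for (i in seq_len(n)) {
    x <- ep$eeg[, i]
    hw <- halfwave_features(x, ep$fs, named)
    hw_count[i, ] <- hw$incidence
    hw_amp[i, ] <- hw$amplitude
    psd <- welch_psd(x, ep$fs)
    for (b in seq_len(nrow(named))) {
      pw[i, b] <- band_power(x, ep$fs, named[b, ], psd = psd)
    }
    total_power[i] <- band_power(x, ep$fs, total, psd = psd)
    rms[i] <- emg_rms(ep$emg[, i])
  }
  out <- data.frame(epoch_index = seq_len(n), clock_time = ep$clock_time,
                    photoperiod = ep$photoperiod, stringsAsFactors = FALSE)
  colnames(hw_count) <- paste0("hw_count_", named$name)
  colnames(hw_amp) <- paste0("hw_amp_", named$name)
  colnames(pw) <- paste0("power_", named$name)
  out <- cbind(out, hw_count, hw_amp, pw,
               data.frame(total_power = total_power, emg_rms = rms,
                          artefact = FALSE))
  rownames(out) <- NULL
  out
}

#' Numeric feature columns used for staging
#' @return character vector of column names in [extract_features()] output.
#' @export
staging_feature_columns <- function() {
  named <- setdiff(band_definitions()$name, "total")
  c(paste0("hw_count_", named), paste0("hw_amp_", named),
    paste0("power_", named), "total_power", "emg_rms")
}
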