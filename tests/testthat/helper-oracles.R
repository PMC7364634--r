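# Independent brute-force oracles. These deliberately use naive
# sample-by-sample / element-by-element loops so they share no code path
# with the package implementations they check.

# Half-wave features by explicit sample scan: centre the signal, walk the
# samples to find strict sign-change crossings, measure each half-wave's
# duration and peak by looping, and bin by equivalent frequency.
oracle_halfwaves <- function(x, fs, bands, min_freq_ceiling = 30) {
  s <- x - mean(x)
  n <- length(s)
  crossings <- integer(0)
  for (i in seq_len(n - 1)) {
    if (s[i] * s[i + 1] < 0) crossings <- c(crossings, i)
  }
  inc <- stats::setNames(rep(0, nrow(bands)), bands$name)
  amp_sum <- inc
  if (length(crossings) >= 2) {
    for (k in seq_len(length(crossings) - 1)) {
      i <- crossings[k]; j <- crossings[k + 1]
      dur <- (j - i) / fs
      if (dur < 1 / (2 * min_freq_ceiling)) next
      f <- 1 / (2 * dur)
      peak <- 0
      for (m in (i + 1):j) peak <- max(peak, abs(s[m]))
      for (b in seq_len(nrow(bands))) {
        if (f > bands$lo[b] && f <= bands$hi[b]) {
          inc[b] <- inc[b] + 1
          amp_sum[b] <- amp_sum[b] + peak
        }
      }
    }
  }
  amp <- ifelse(inc > 0, amp_sum / inc, NA_real_)
  names(amp) <- bands$name
  list(incidence = inc, amplitude = amp)
}

# Bout detection by explicit epoch walk (no rle).
oracle_bouts <- function(labels, epoch_seconds = 10, min_sleep_epochs = 3) {
  n <- length(labels)
  res <- list()
  # maximal sleep runs
  i <- 1
  while (i <= n) {
    if (labels[i] %in% c("NREM", "REM")) {
      j <- i
      while (j < n && labels[j + 1] %in% c("NREM", "REM")) j <- j + 1
      # check content: >=3 consecutive NREM or >=2 consecutive REM
      best_n <- 0; best_r <- 0; run <- 0; cur <- ""
      for (k in i:j) {
        if (labels[k] == cur) run <- run + 1 else { cur <- labels[k]; run <- 1 }
        if (cur == "NREM") best_n <- max(best_n, run)
        if (cur == "REM") best_r <- max(best_r, run)
      }
      if ((best_n >= 3 || best_r >= 2) && (j - i + 1) >= min_sleep_epochs) {
        res[[length(res) + 1]] <- data.frame(kind = "SLEEP", start_epoch = i,
                                             n_epochs = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  i <- 1
  while (i <= n) {
    if (labels[i] == "REM") {
      j <- i
      while (j < n && labels[j + 1] == "REM") j <- j + 1
      if (j - i + 1 >= 2) {
        res[[length(res) + 1]] <- data.frame(kind = "REM", start_epoch = i,
                                             n_epochs = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(res)) {
    return(data.frame(kind = character(), start_epoch = integer(),
                      n_epochs = integer(), duration_s = numeric()))
  }
  out <- do.call(rbind, res)
  out$duration_s <- out$n_epochs * epoch_seconds
  out <- out[order(out$kind, out$start_epoch), ]
  rownames(out) <- NULL
  out
}

# Ranked-membership classification by materialising the full
# feature x state rank matrix with explicit counting, then applying the
# same EMG overrides.
oracle_rank_classify <- function(features, templates) {
  st <- arousal_states()
  tie_order <- c("NREM", "REM", "THETA_WAKE", "WAKE")
  cols <- templates$feature_names
  out <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    x <- as.numeric(features[i, cols])
    x[is.na(x)] <- 0
    z <- (x - templates$centre) / templates$spread
    rank_mat <- matrix(0, 4, length(cols))
    dmat <- matrix(0, 4, length(cols))
    for (s in 1:4) {
      for (f in seq_along(cols)) {
        dmat[s, f] <- abs(z[f] - templates$centroids[st[s], cols[f]])
      }
    }
    for (f in seq_along(cols)) {
      for (s in 1:4) {
        smaller <- 0
        for (s2 in 1:4) if (dmat[s2, f] < dmat[s, f]) smaller <- smaller + 1
        rank_mat[s, f] <- smaller + 1      # ties share the minimum rank
      }
    }
    mean_rank <- rowMeans(rank_mat)
    best <- which(mean_rank == min(mean_rank))
    if (length(best) > 1) {
      d2 <- sapply(best, function(s) sum(dmat[s, ]^2))
      best <- best[d2 == min(d2)]
      if (length(best) > 1) best <- best[order(match(st[best], tie_order))][1]
    }
    lab <- st[best[1]]
    emg <- as.numeric(features[i, "emg_rms"])
    if (lab == "REM" && emg > templates$emg_atonia_threshold) {
      lab <- "THETA_WAKE"
    } else if (lab %in% c("WAKE", "THETA_WAKE") &&
               emg < templates$emg_atonia_threshold &&
               as.numeric(features[i, "power_theta"]) >
                 as.numeric(features[i, "power_delta"])) {
      lab <- "REM"
    }
    out[i] <- lab
  }
  out
}

# Changed-pixel count by explicit per-pixel double loop.
oracle_frame_motion <- function(prev, cur, grey_delta_min = 10) {
  count <- 0L
  for (r in seq_len(nrow(prev))) {
    for (c in seq_len(ncol(prev))) {
      if (abs(cur[r, c] - prev[r, c]) >= grey_delta_min) count <- count + 1L
    }
  }
  count
}

# Random hypnogram labels, optionally including artefacts.
random_labels <- function(n, p_artefact = 0) {
  pool <- arousal_states()
  labs <- sample(pool, n, replace = TRUE)
  if (p_artefact > 0) {
    k <- rbinom(1, n, p_artefact)
    if (k > 0) labs[sample.int(n, k)] <- "ARTEFACT"
  }
  labs
}
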