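## Sleep architecture and continuity metrics: bout detection, time in
## state per photoperiod, REM episode distribution, circadian amplitude,
## weekly aggregation.

#' Detect sleep and REM bouts in a hypnogram
#'
#' Sleep bouts are maximal runs of sleep epochs (NREM plus REM) that
#' qualify under the study rule: the run contains at least 3 consecutive
#' NREM epochs or at least 2 consecutive REM epochs, and spans at least
#' `min_sleep_epochs` epochs in total (default 3, so the shortest reported
#' sleep bout is 30 s — the "> 30 s duration" convention; set it to 2 for
#' the literal reading under which an isolated 2-epoch REM run is a 20-s
#' sleep bout). REM bouts are maximal runs of REM with length >= 2.
#' ARTEFACT epochs break runs. Under `sleep_rule = "nrem_only"` a sleep
#' run qualifies only via its NREM content (the alternative reading).
#'
#' @param hypnogram a `hypnogram`.
#' @param sleep_rule `"run"` (default) or `"nrem_only"`.
#' @param min_sleep_epochs minimum total length of a qualifying sleep run.
#' @return data.frame with columns `kind` ("SLEEP"/"REM"), `start_epoch`,
#'   `n_epochs`, `duration_s`.
#' @export
detect_bouts <- function(hypnogram, sleep_rule = c("run", "nrem_only"),
                         min_sleep_epochs = 3) {
  sleep_rule <- match.arg(sleep_rule)
  labs <- hypnogram$labels
  ep <- hypnogram$epoch_seconds
  out <- list()
  if (length(labs)) {
    is_sleep <- labs %in% c("NREM", "REM")
    r <- rle(is_sleep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- labs[starts[k]:ends[k]]
      rs <- rle(seg)
      has_nrem3 <- any(rs$values == "NREM" & rs$lengths >= 3)
      has_rem2 <- any(rs$values == "REM" & rs$lengths >= 2)
      ok <- if (sleep_rule == "run") has_nrem3 || has_rem2 else has_nrem3
      ok <- ok && r$lengths[k] >= min_sleep_epochs
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "SLEEP", start_epoch = starts[k],
          n_epochs = r$lengths[k], stringsAsFactors = FALSE)
      }
    }
    rr <- rle(labs == "REM")
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    for (k in which(rr$values & rr$lengths >= 2)) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "REM", start_epoch = starts[k],
        n_epochs = rr$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), start_epoch = integer(),
                      n_epochs = integer(), duration_s = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$duration_s <- res$n_epochs * ep
  res <- res[order(res$kind, res$start_epoch), ]
  rownames(res) <- NULL
  res
}

#' Time in state per photoperiod
#'
#' State percentages over scorable (non-ARTEFACT) epochs, separately for
#' the light and dark phases; theta-dominated wake counts as wake. A phase
#' with no scorable epochs is flagged undefined.
#'
#' @param hypnogram a `hypnogram` with schedule attached.
#' @return data.frame, one row per photoperiod: `photoperiod`, `pct_wake`,
#'   `pct_nrem`, `pct_rem`, `min_wake`, `min_nrem`, `min_rem`,
#'   `n_scorable_epochs`, `undefined`.
#' @export
time_in_state <- function(hypnogram) {
  clock <- hypnogram_clock(hypnogram)
  phase <- photoperiod_of(clock, hypnogram$schedule)
  labs <- hypnogram$labels
  rows <- lapply(c("LIGHT", "DARK"), function(ph) {
    sel <- phase == ph & labs != "ARTEFACT"
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(photoperiod = ph, pct_wake = NA_real_,
                        pct_nrem = NA_real_, pct_rem = NA_real_,
                        min_wake = NA_real_, min_nrem = NA_real_,
                        min_rem = NA_real_, n_scorable_epochs = 0L,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    l <- labs[sel]
    wk <- sum(l %in% c("WAKE", "THETA_WAKE"))
    nr <- sum(l == "NREM")
    rm_ <- sum(l == "REM")
    mins <- hypnogram$epoch_seconds / 60
    data.frame(photoperiod = ph, pct_wake = 100 * wk / n,
               pct_nrem = 100 * nr / n, pct_rem = 100 * rm_ / n,
               min_wake = wk * mins, min_nrem = nr * mins,
               min_rem = rm_ * mins, n_scorable_epochs = n,
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distribution of REM episode lengths
#'
#' Counts all maximal REM runs by length, including the single-epoch
#' episodes that fall below the bout criterion — the quantity that reveals
#' REM fragmentation when total REM time is preserved.
#'
#' @param hypnogram a `hypnogram`.
#' @return named integer vector: names are run lengths (epochs), values are
#'   counts. Empty when there is no REM.
#' @export
rem_episode_distribution <- function(hypnogram) {
  r <- rle(hypnogram$labels == "REM")
  lens <- r$lengths[r$values]
  if (!length(lens)) return(stats::setNames(integer(0), character(0)))
  tab <- table(lens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Circadian NREM amplitude
#'
#' Signed light-minus-dark difference in NREM percentage for one
#' animal-week, in percentage points.
#'
#' @param light_metrics,dark_metrics single rows of period metrics with
#'   `pct_nrem` and `excluded`/`undefined` flags.
#' @return numeric percentage points.
#' @export
circadian_amplitude <- function(light_metrics, dark_metrics) {
  excl <- function(m) isTRUE(m$excluded) || isTRUE(m$undefined)
  abort_if(excl(light_metrics) || excl(dark_metrics),
           "cannot compute circadian amplitude from excluded periods")
  light_metrics$pct_nrem - dark_metrics$pct_nrem
}

#' Aggregate daily metrics to one animal-week row per photoperiod
#'
#' Unweighted mean across retained (non-excluded) days; a week with no
#' retained day is marked excluded and its values set missing.
#'
#' @param daily data.frame of per-day period metrics with columns
#'   `animal_id`, `age_week`, `photoperiod`, numeric outcome columns, and
#'   an `excluded` logical.
#' @return data.frame with one row per animal x week x photoperiod.
#' @export
weekly_aggregate <- function(daily) {
  abort_if(!all(c("animal_id", "age_week", "photoperiod") %in%
                  colnames(daily)),
           "daily metrics need animal_id, age_week, photoperiod columns")
  if (!"excluded" %in% colnames(daily)) daily$excluded <- FALSE
  num_cols <- setdiff(names(daily)[vapply(daily, is.numeric, logical(1))],
                      c("age_week"))
  key <- interaction(daily$animal_id, daily$age_week, daily$photoperiod,
                     drop = TRUE)
  rows <- lapply(split(daily, key), function(d) {
    keep <- d[!d$excluded, , drop = FALSE]
    out <- d[1, c("animal_id", "age_week", "photoperiod"), drop = FALSE]
    if (nrow(keep) == 0) {
      out[num_cols] <- NA_real_
      out$excluded <- TRUE
    } else {
      out[num_cols] <- lapply(keep[num_cols], mean)
      out$excluded <- FALSE
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Full period metrics for one scored animal-week
#'
#' Convenience composition: bouts, time in state and (optionally) band
#' powers per photoperiod from a hypnogram plus its epoch features.
#'
#' @param hypnogram a `hypnogram`.
#' @param features optional [extract_features()] output aligned to the
#'   hypnogram (for band-power means).
#' @param animal_id,group,age_week metadata for the output rows.
#' @return data.frame, one row per photoperiod, with state percentages,
#'   bout counts and mean lengths, and band-power means when features are
#'   given.
#' @export
period_metrics <- function(hypnogram, features = NULL,
                           animal_id = "a1", group = "WT", age_week = 20) {
  tis <- time_in_state(hypnogram)
  clock <- hypnogram_clock(hypnogram)
  phase <- photoperiod_of(clock, hypnogram$schedule)
  rows <- lapply(seq_len(nrow(tis)), function(i) {
    ph <- tis$photoperiod[i]
    sub_labels <- hypnogram$labels
    sub_labels[phase != ph] <- "ARTEFACT"   # out-of-phase epochs break runs
    hy <- new_hypnogram(sub_labels, hypnogram$epoch_seconds,
                        hypnogram$start_clock_time, hypnogram$schedule)
    bouts <- detect_bouts(hy)
    sb <- bouts[bouts$kind == "SLEEP", ]
    rb <- bouts[bouts$kind == "REM", ]
    out <- data.frame(animal_id = animal_id, group = group,
                      age_week = age_week, photoperiod = ph,
                      stringsAsFactors = FALSE)
    out <- cbind(out, tis[i, c("pct_wake", "pct_nrem", "pct_rem",
                               "n_scorable_epochs")])
    out$sleep_bout_count <- nrow(sb)
    out$sleep_bout_mean_len_s <- if (nrow(sb)) mean(sb$duration_s) else NA_real_
    out$rem_bout_count <- nrow(rb)
    out$rem_bout_mean_len_s <- if (nrow(rb)) mean(rb$duration_s) else NA_real_
    if (!is.null(features)) {
      sel <- phase == ph & hypnogram$labels != "ARTEFACT"
      nrem_sel <- sel & hypnogram$labels == "NREM"
      for (b in setdiff(band_definitions()$name, "total")) {
        out[[paste0("power_", b)]] <- mean(features[[paste0("power_", b)]][sel])
      }
      out$total_power <- mean(features$total_power[sel])
      out$nrem_delta_power <- if (any(nrem_sel)) {
        mean(features$power_delta[nrem_sel])
      } else NA_real_
    }
    out$excluded <- tis$undefined[i]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
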