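## Synthetic cohort generator: circadian Markov hypnograms, state-conditional
## EEG/EMG synthesis, artefact injection, home-cage video, and full
## longitudinal study datasets with a progressive transgenic phenotype.

#' Photoperiod schedule
#'
#' Describes the light/dark cycle of the holding room. The default is the
#' standard 12:12 schedule with lights on at 06:00.
#'
#' @param lights_on clock time (hours, 0-24) at which lights switch on.
#' @param light_hours duration of the light phase (hours).
#' @param dark_hours duration of the dark phase (hours).
#' @return an object of class `photoperiod_schedule`.
#' @export
photoperiod_schedule <- function(lights_on = 6, light_hours = 12,
                                 dark_hours = 12) {
  abort_if(light_hours <= 0 || dark_hours <= 0,
           "light and dark phases must both be positive")
  abort_if(abs(light_hours + dark_hours - 24) > 1e-9,
           "light_hours + dark_hours must equal 24")
  structure(list(lights_on = lights_on %% 24, light_hours = light_hours,
                 dark_hours = dark_hours),
            class = "photoperiod_schedule")
}

#' Is a clock time in the light phase?
#'
#' @param clock_time clock time(s) in hours (any real; wrapped mod 24).
#' @param schedule a [photoperiod_schedule()].
#' @return logical vector, `TRUE` for LIGHT.
#' @export
is_light <- function(clock_time, schedule) {
  ((clock_time - schedule$lights_on) %% 24) < schedule$light_hours
}

#' Photoperiod label for clock times
#' @inheritParams is_light
#' @return character vector, `"LIGHT"` or `"DARK"`.
#' @export
photoperiod_of <- function(clock_time, schedule) {
  ifelse(is_light(clock_time, schedule), "LIGHT", "DARK")
}

#' State spectrum specifications
#'
#' Per-state EEG band-power targets (delta/theta/alpha/beta, in uV^2) and EMG
#' tone (RMS, arbitrary units) used by the signal synthesiser. Defaults encode
#' the standard rodent signatures the stager relies on: NREM is
#' delta-dominated with moderate muscle tone, REM and theta-dominated wake
#' share a 5-9 Hz theta rhythm and are separated only by EMG (REM atonia),
#' and quiet wake is low-amplitude broadband with high EMG.
#'
#' @param amplitude_scale unitless multiplier applied to the EEG waveform
#'   (power scales with its square), modelling electrode signal amplitude.
#' @return named list (one element per state) of specs with fields
#'   `band_power_targets`, `emg_tone`, `amplitude_scale`.
#' @export
state_spectrum_specs <- function(amplitude_scale = 1) {
  abort_if(amplitude_scale < 0, "amplitude_scale must be >= 0")
  tgt <- function(delta, theta, alpha, beta) {
    c(delta = delta, theta = theta, alpha = alpha, beta = beta)
  }
  specs <- list(
    WAKE       = list(band_power_targets = tgt(30, 30, 15, 15), emg_tone = 6),
    THETA_WAKE = list(band_power_targets = tgt(20, 100, 15, 10), emg_tone = 6),
    NREM       = list(band_power_targets = tgt(200, 30, 10, 5), emg_tone = 1),
    REM        = list(band_power_targets = tgt(20, 100, 10, 5), emg_tone = 0.3)
  )
  lapply(specs, function(s) {
    s$amplitude_scale <- amplitude_scale
    s
  })
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P row-stochastic square matrix.
#' @return probability vector, named like the rows of `P`.
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

check_stochastic <- function(P) {
  abort_if(!is.matrix(P) || nrow(P) != ncol(P),
           "transition matrix must be square")
  abort_if(any(P < -1e-12),
           "transition matrix has negative entries")
  abort_if(any(abs(rowSums(P) - 1) > 1e-8),
           "transition matrix rows must each sum to 1 (row-stochastic)")
  invisible(P)
}

#' Default circadian transition matrices
#'
#' Two 4-state transition matrices (10-s epoch resolution), one per
#' photoperiod phase. The light-phase chain favours sleep and the dark-phase
#' chain favours wake, reproducing the strong circadian sleep placement of
#' laboratory mice.
#'
#' @return list with elements `light` and `dark`, each a 4x4 row-stochastic
#'   matrix over `arousal_states()`.
#' @export
default_transition_matrices <- function() {
  st <- arousal_states()
  light <- matrix(c(
    # WAKE  THETA  NREM   REM
    0.70, 0.05, 0.24, 0.01,   # WAKE
    0.30, 0.55, 0.14, 0.01,   # THETA_WAKE
    0.08, 0.01, 0.85, 0.06,   # NREM
    0.15, 0.02, 0.08, 0.75    # REM
  ), nrow = 4, byrow = TRUE, dimnames = list(st, st))
  dark <- matrix(c(
    0.880, 0.050, 0.065, 0.005,
    0.350, 0.580, 0.060, 0.010,
    0.120, 0.020, 0.800, 0.060,
    0.200, 0.030, 0.070, 0.700
  ), nrow = 4, byrow = TRUE, dimnames = list(st, st))
  list(light = light, dark = dark)
}

#' Tilt a transition matrix towards more wake
#'
#' Mixes `P` with a wake-absorbing kernel and solves for the mixing weight
#' that raises the stationary wake fraction (WAKE + THETA_WAKE) by
#' `wake_pp` percentage points. Used to encode a progressive dark-phase
#' wake increase.
#'
#' @param P 4x4 row-stochastic matrix over `arousal_states()`.
#' @param wake_pp percentage points of additional stationary wake.
#' @return adjusted row-stochastic matrix.
#' @export
increase_wake_fraction <- function(P, wake_pp) {
  check_stochastic(P)
  if (wake_pp <= 0) return(P)
  wake_frac <- function(M) {
    pi <- stationary_distribution(M)
    unname(pi["WAKE"] + pi["THETA_WAKE"])
  }
  base <- wake_frac(P)
  target <- min(base + wake_pp / 100, 0.995)
  Q <- matrix(0, 4, 4, dimnames = dimnames(P))
  Q[, "WAKE"] <- 1
  f <- function(a) wake_frac((1 - a) * P + a * Q) - target
  a <- stats::uniroot(f, c(0, 1), tol = 1e-9)$root
  (1 - a) * P + a * Q
}

#' Shrink the REM continuation probability
#'
#' Multiplies the REM self-transition probability by `mult` and redistributes
#' the freed mass over the other exits in proportion, fragmenting REM into
#' shorter episodes without changing where REM exits go.
#'
#' @param P 4x4 row-stochastic matrix over `arousal_states()`.
#' @param mult multiplier in (0, 1] on P\["REM","REM"\].
#' @return adjusted row-stochastic matrix.
#' @export
fragment_rem <- function(P, mult) {
  check_stochastic(P)
  abort_if(mult <= 0 || mult > 1, "REM continuation multiplier must be in (0,1]")
  p0 <- P["REM", "REM"]
  p1 <- p0 * mult
  other <- P["REM", setdiff(colnames(P), "REM")]
  P["REM", "REM"] <- p1
  P["REM", setdiff(colnames(P), "REM")] <- other / sum(other) * (1 - p1)
  P
}

#' Simulate a hypnogram from a circadian Markov chain
#'
#' Draws one arousal-state label per epoch from a two-phase Markov chain:
#' the light-phase matrix is used for epochs whose start clock time falls in
#' the light phase and the dark-phase matrix otherwise.
#'
#' @param schedule a [photoperiod_schedule()].
#' @param transition list with `light` and `dark` row-stochastic matrices
#'   over `arousal_states()`.
#' @param duration_hours recording duration; must be a positive multiple of
#'   the epoch length.
#' @param epoch_seconds epoch length (s), default 10.
#' @param start_clock_time clock time (hours) of the first epoch; defaults to
#'   lights-on.
#' @param seed integer seed; the same spec and seed give a bitwise-identical
#'   label sequence.
#' @return an object of class `hypnogram`: list with `labels`,
#'   `epoch_seconds`, `start_clock_time`, `schedule`.
#' @export
simulate_hypnogram <- function(schedule, transition, duration_hours,
                               epoch_seconds = 10,
                               start_clock_time = schedule$lights_on,
                               seed = 1) {
  st <- arousal_states()
  abort_if(!all(c("light", "dark") %in% names(transition)),
           "transition must contain `light` and `dark` matrices")
  for (P in transition[c("light", "dark")]) {
    check_stochastic(P)
    abort_if(!identical(rownames(P), st),
             "transition matrices must be over arousal_states() in order")
  }
  n_epochs <- duration_hours * 3600 / epoch_seconds
  abort_if(duration_hours <= 0 || abs(n_epochs - round(n_epochs)) > 1e-9,
           "duration must be a positive multiple of the epoch length")
  n_epochs <- as.integer(round(n_epochs))
  clock <- (start_clock_time + (seq_len(n_epochs) - 1) * epoch_seconds / 3600) %% 24
  light <- is_light(clock, schedule)

  labels <- with_seed(seed, {
    out <- integer(n_epochs)
    P0 <- if (light[1]) transition$light else transition$dark
    out[1] <- sample.int(4L, 1L, prob = stationary_distribution(P0))
    if (n_epochs > 1L) {
      u <- stats::runif(n_epochs - 1L)
      cl <- rbind(t(apply(transition$light, 1, cumsum)),
                  t(apply(transition$dark, 1, cumsum)))
      for (i in 2:n_epochs) {
        row <- out[i - 1L] + (if (light[i]) 0L else 4L)
        out[i] <- findInterval(u[i - 1L], cl[row, ], left.open = TRUE) + 1L
      }
    }
    st[out]
  })
  new_hypnogram(labels, epoch_seconds, start_clock_time, schedule)
}

#' Construct a hypnogram object
#'
#' @param labels character vector of state labels (`arousal_states()` plus
#'   optionally `"ARTEFACT"`).
#' @param epoch_seconds epoch length (s).
#' @param start_clock_time clock time (hours) of the first epoch.
#' @param schedule a [photoperiod_schedule()].
#' @return object of class `hypnogram`.
#' @export
new_hypnogram <- function(labels, epoch_seconds = 10,
                          start_clock_time = 6,
                          schedule = photoperiod_schedule()) {
  ok <- c(arousal_states(), "ARTEFACT")
  abort_if(!all(labels %in% ok),
           sprintf("hypnogram labels must be in {%s}", paste(ok, collapse = ", ")))
  structure(list(labels = labels, epoch_seconds = epoch_seconds,
                 start_clock_time = start_clock_time, schedule = schedule),
            class = "hypnogram")
}

#' Epoch start clock times of a hypnogram
#' @param hypnogram a `hypnogram`.
#' @return numeric vector of clock times (hours mod 24), one per epoch.
#' @export
hypnogram_clock <- function(hypnogram) {
  n <- length(hypnogram$labels)
  (hypnogram$start_clock_time +
     (seq_len(n) - 1) * hypnogram$epoch_seconds / 3600) %% 24
}

#' Synthesize EEG and EMG signals for a hypnogram
#'
#' Each epoch's EEG is a sum of band-limited oscillators (a few random-phase
#' sinusoids per band) whose total variance meets that state's band-power
#' targets, scaled by `amplitude_scale`; the EMG is white noise normalised to
#' the state's RMS tone. Epoch-to-epoch frequency and amplitude jitter gives
#' realistic sampling variability while keeping the long-run Welch band power
#' on target.
#'
#' @param hypnogram a `hypnogram` (no ARTEFACT labels).
#' @param specs per-state specs from [state_spectrum_specs()].
#' @param fs sampling rate (Hz), >= 100.
#' @param seed integer seed.
#' @param noise_floor_uv standard deviation (uV) of additive white
#'   instrument noise, applied after amplitude scaling (default 0: a pure
#'   oscillator generator whose all-zero targets give an exactly zero
#'   signal). A positive floor models amplifier noise that does not shrink
#'   with electrode signal amplitude — the regime in which scoring degrades
#'   as the EEG amplitude declines.
#' @param animal_id,group,age_week metadata carried on the recording.
#' @return an object of class `recording`: list with `eeg`, `emg` (numeric),
#'   `fs`, `start_clock_time`, `schedule`, `animal_id`, `group`, `age_week`.
#' @export
synthesize_signals <- function(hypnogram, specs = state_spectrum_specs(),
                               fs = 400, seed = 1, noise_floor_uv = 0,
                               animal_id = "a1", group = "WT", age_week = 20) {
  abort_if(fs < 100, "fs must be >= 100 Hz")
  labs <- hypnogram$labels
  abort_if(!all(labs %in% names(specs)),
           "every hypnogram label needs a state spectrum spec")
  ep <- hypnogram$epoch_seconds
  nsamp <- as.integer(round(ep * fs))
  bands <- list(delta = c(1, 4), theta = c(5.1, 9),
                alpha = c(9.1, 12), beta = c(12, 20))
  tt <- (seq_len(nsamp) - 1) / fs

  eeg <- with_seed(seed, {
    out <- numeric(length(labs) * nsamp)
    for (i in seq_along(labs)) {
      sp <- specs[[labs[i]]]
      x <- numeric(nsamp)
      for (b in names(bands)) {
        pw <- sp$band_power_targets[[b]]
        if (pw <= 0) next
        m <- 3L
        f <- stats::runif(m, bands[[b]][1] + 0.2, bands[[b]][2] - 0.2)
        ph <- stats::runif(m, 0, 2 * pi)
        jit <- stats::runif(1, 0.95, 1.05)
        amp <- sqrt(2 * pw * jit / m)
        for (k in seq_len(m)) x <- x + amp * sin(2 * pi * f[k] * tt + ph[k])
      }
      out[((i - 1) * nsamp + 1):(i * nsamp)] <- x * sp$amplitude_scale
    }
    if (noise_floor_uv > 0) {
      out <- out + stats::rnorm(length(out), 0, noise_floor_uv)
    }
    out
  })
  emg <- with_seed(seed + 1L, {
    out <- numeric(length(labs) * nsamp)
    for (i in seq_along(labs)) {
      tone <- specs[[labs[i]]]$emg_tone
      if (tone > 0) {
        z <- stats::rnorm(nsamp)
        out[((i - 1) * nsamp + 1):(i * nsamp)] <- z * tone / sqrt(mean(z^2))
      }
      # zero tone -> exact zeros
    }
    out
  })
  new_recording(eeg, emg, fs,
                start_clock_time = hypnogram$start_clock_time,
                schedule = hypnogram$schedule,
                animal_id = animal_id, group = group, age_week = age_week)
}

#' Inject clipping and flat-line artefacts into a recording
#'
#' Clipped epochs are driven into the rails: the EEG is amplified and
#' saturated at +/- `rail` so that well over 10% of samples sit on the rail.
#' Flat epochs are replaced by a constant (zero variance). The ground-truth
#' artefact mask is returned alongside the modified recording.
#'
#' @param recording a `recording`.
#' @param clip_epochs integer indices of epochs to clip (1-based).
#' @param flat_epochs integer indices of epochs to flatten; must be disjoint
#'   from `clip_epochs`.
#' @param rail saturation amplitude (uV).
#' @param epoch_seconds epoch length (s).
#' @return list with `recording` (modified), `mask` (logical per epoch) and
#'   `reason` (character per epoch: "", "CLIP" or "FLAT").
#' @export
inject_artefacts <- function(recording, clip_epochs = integer(),
                             flat_epochs = integer(), rail = 400,
                             epoch_seconds = 10) {
  abort_if(length(intersect(clip_epochs, flat_epochs)) > 0,
           "clip and flat epoch sets must be disjoint")
  nsamp <- as.integer(round(epoch_seconds * recording$fs))
  n_ep <- length(recording$eeg) %/% nsamp
  abort_if(any(c(clip_epochs, flat_epochs) < 1) ||
             any(c(clip_epochs, flat_epochs) > n_ep),
           "artefact epoch indices out of range")
  eeg <- recording$eeg
  for (i in clip_epochs) {
    idx <- ((i - 1) * nsamp + 1):(i * nsamp)
    x <- eeg[idx]
    mx <- max(abs(x))
    if (mx < .Machine$double.eps) {
      # degenerate zero epoch: synthesize a railed square wave
      x <- rail * rep_len(c(1, -1), nsamp)
    } else {
      x <- pmin(pmax(3 * rail / mx * x, -rail), rail)
    }
    eeg[idx] <- x
  }
  for (i in flat_epochs) {
    idx <- ((i - 1) * nsamp + 1):(i * nsamp)
    eeg[idx] <- 0
  }
  mask <- rep(FALSE, n_ep)
  reason <- rep("", n_ep)
  mask[clip_epochs] <- TRUE
  reason[clip_epochs] <- "CLIP"
  mask[flat_epochs] <- TRUE
  reason[flat_epochs] <- "FLAT"
  recording$eeg <- eeg
  list(recording = recording, mask = mask, reason = reason)
}

#' Trajectory specification for one treatment group
#'
#' Encodes the progressive phenotype: a multiplicative EEG amplitude/power
#' decline per 4-week cycle after `onset_week`, a dark-phase wake increase
#' (percentage points per cycle), REM fragmentation (multiplier per cycle on
#' the REM continuation probability) and a fractional motion increase per
#' cycle. Untreated controls have all-zero rates.
#'
#' @param group one of `"WT"`, `"tTA"`, `"Tg"`, `"TgDOX"`.
#' @param power_decline_rate fractional power decline per cycle, in \[0, 1\].
#' @param onset_week age (weeks) at which progression starts.
#' @param dark_wake_increase percentage points of dark-phase wake per cycle.
#' @param wake_onset_week age (weeks) at which the wake/NREM change starts;
#'   defaults to `onset_week`. In the progressive phenotype the sleep-wake
#'   redistribution follows the spectral decline, so the transgenic default
#'   lags the power onset by two cycles.
#' @param rem_fragmentation_rate per-cycle multiplier on REM continuation
#'   probability, in (0, 1\].
#' @param motion_increase fractional dark-phase motion increase per cycle.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(group, power_decline_rate = 0, onset_week = 20,
                            dark_wake_increase = 0,
                            wake_onset_week = onset_week,
                            rem_fragmentation_rate = 1, motion_increase = 0) {
  abort_if(power_decline_rate < 0 || power_decline_rate > 1,
           "power_decline_rate must be in [0,1]")
  abort_if(rem_fragmentation_rate <= 0 || rem_fragmentation_rate > 1,
           "rem_fragmentation_rate must be in (0,1]")
  structure(list(group = group, power_decline_rate = power_decline_rate,
                 onset_week = onset_week,
                 dark_wake_increase = dark_wake_increase,
                 wake_onset_week = wake_onset_week,
                 rem_fragmentation_rate = rem_fragmentation_rate,
                 motion_increase = motion_increase),
            class = "trajectory_spec")
}

#' Default group trajectories
#'
#' The transgenic (Tg) group progresses from week 20: band power declines 10%
#' per 4-week cycle and REM continuation probability shrinks by 15% per
#' cycle from week 20, while the sleep-wake redistribution follows the
#' spectral decline — dark-phase wake rises 2.5 percentage points per cycle
#' from week 28 — and dark-phase motion rises 8% per cycle. Wild-type, transactivator-only and
#' doxycycline-suppressed groups are flat.
#'
#' @return named list of [trajectory_spec()]s for WT, tTA, Tg, TgDOX.
#' @export
default_trajectories <- function() {
  list(
    WT    = trajectory_spec("WT"),
    tTA   = trajectory_spec("tTA"),
    Tg    = trajectory_spec("Tg", power_decline_rate = 0.10, onset_week = 20,
                            dark_wake_increase = 2.5, wake_onset_week = 28,
                            rem_fragmentation_rate = 0.85,
                            motion_increase = 0.08),
    TgDOX = trajectory_spec("TgDOX")
  )
}

#' Cohort specification
#'
#' @param n_per_group animals per treatment group (>= 2).
#' @param ages observation ages in weeks, strictly increasing; default the
#'   seven 4-week cycles spanning weeks 20-44.
#' @param seed integer master seed for the whole study.
#' @param epoch_seconds scoring epoch (s).
#' @param fs sampling rate (Hz) for any synthesized signals.
#' @param atrophy_link per-group terminal thickness distribution
#'   (`mean_mm`, `sd_mm`) plus `coupling`, the within-group correlation
#'   between realised phenotype severity and thickness.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 12, ages = seq(20, 44, by = 4),
                        seed = 1, epoch_seconds = 10, fs = 400,
                        atrophy_link = default_atrophy_link()) {
  abort_if(n_per_group < 2, "n_per_group must be >= 2")
  abort_if(any(diff(ages) <= 0), "ages must be strictly increasing")
  structure(list(n_per_group = n_per_group, ages = ages, seed = seed,
                 epoch_seconds = epoch_seconds, fs = fs,
                 atrophy_link = atrophy_link),
            class = "cohort_spec")
}

#' Default atrophy link
#'
#' Terminal summed bilateral hippocampus + cortex thickness (mm) per group:
#' marked atrophy in Tg, near-control thickness under doxycycline
#' suppression; `coupling` ties within-group thickness to realised phenotype
#' severity.
#'
#' @return list of per-group `c(mean_mm, sd_mm)` plus `coupling`.
#' @export
default_atrophy_link <- function() {
  list(WT = c(mean_mm = 6.0, sd_mm = 0.25),
       tTA = c(mean_mm = 5.9, sd_mm = 0.25),
       Tg = c(mean_mm = 4.4, sd_mm = 0.35),
       TgDOX = c(mean_mm = 5.7, sd_mm = 0.30),
       coupling = 0.6)
}

## baseline outcome levels per photoperiod, derived from the default chain's
## stationary distributions and state band-power targets
baseline_outcomes <- function() {
  mats <- default_transition_matrices()
  specs <- state_spectrum_specs()
  per_phase <- function(P) {
    pi <- stationary_distribution(P)
    bp <- sapply(c("delta", "theta", "alpha", "beta"), function(b) {
      sum(pi * sapply(specs, function(s) s$band_power_targets[[b]]))
    })
    list(pct_wake = 100 * unname(pi["WAKE"] + pi["THETA_WAKE"]),
         pct_nrem = 100 * unname(pi["NREM"]),
         pct_rem = 100 * unname(pi["REM"]),
         band_power = bp,
         rem_continuation = P["REM", "REM"])
  }
  list(LIGHT = per_phase(mats$light), DARK = per_phase(mats$dark),
       motion = c(LIGHT = 2e4, DARK = 8e4))
}

#' Simulate a longitudinal study dataset
#'
#' Generates a full cohort (four groups, seven ages by default) of weekly
#' truth metrics at the animal x age x photoperiod level, plus per-animal
#' terminal atrophy values coupled to realised phenotype severity, and
#' optionally truth hypnograms and raw signals for a subset of the design.
#'
#' The metric model: band powers start at the level implied by the default
#' state targets and stationary occupancy, carry a lognormal animal intercept
#' (sd 0.15 on the log scale) and week-to-week lognormal noise (sd 0.10), and
#' decline multiplicatively by the group's `power_decline_rate` per cycle
#' after onset. State percentages start at the stationary split, with a
#' per-animal intercept (sd 2 pp) and weekly noise (sd 2.5 pp); the
#' dark-phase wake increase is taken from NREM. REM continuity follows the
#' geometric run-length model at the trajectory's continuation probability.
#' Motion is lognormal around phase baselines with the trajectory's
#' multiplicative increase.
#'
#' @param cohort a [cohort_spec()].
#' @param trajectories named list of [trajectory_spec()], one per group.
#' @param groups treatment groups to simulate.
#' @param hypnogram_hours hours of truth hypnogram to simulate per
#'   animal-week (0 to skip; hypnograms are only needed for staging/QC-level
#'   analyses, not for the metric-level statistics).
#' @param signal_hours hours of raw EEG/EMG to synthesize per animal-week
#'   (0 to skip; full-rate signals for a whole cohort are far larger than any
#'   analysis here needs).
#' @return list of class `study_dataset` with `metrics` (long data.frame:
#'   animal_id, group, age_week, photoperiod, outcome, value), `atrophy`
#'   (animal_id, group, thickness_mm), and optionally `hypnograms`,
#'   `recordings` (nested lists keyed by animal and age).
#' @export
simulate_study <- function(cohort = cohort_spec(),
                           trajectories = default_trajectories(),
                           groups = c("WT", "tTA", "Tg", "TgDOX"),
                           hypnogram_hours = 0, signal_hours = 0) {
  abort_if(!all(groups %in% names(trajectories)),
           "every group needs a trajectory spec")
  base <- baseline_outcomes()
  ages <- cohort$ages
  link <- cohort$atrophy_link
  coupling <- link$coupling

  res <- with_seed(cohort$seed, {
    rows <- list()
    atr <- list()
    hyps <- list()
    recs <- list()
    for (g in groups) {
      tr <- trajectories[[g]]
      for (a in seq_len(cohort$n_per_group)) {
        id <- sprintf("%s_%02d", g, a)
        pow_int <- stats::rlnorm(1, 0, 0.15)      # animal power intercept
        pct_int <- stats::rnorm(1, 0, 2)          # animal state-% intercept
        rate_i <- tr$power_decline_rate *
          exp(stats::rnorm(1, 0, 0.15) - 0.15^2 / 2)
        rate_i <- min(max(rate_i, 0), 1)
        sev <- 0                                   # realised severity proxy
        for (w in ages) {
          cyc <- max(0, (w - tr$onset_week) / 4)
          wake_cyc <- max(0, (w - tr$wake_onset_week) / 4)
          scale2 <- (1 - rate_i)^cyc               # power multiplier
          for (ph in c("LIGHT", "DARK")) {
            b <- base[[ph]]
            dark <- ph == "DARK"
            wake_shift <- if (dark) tr$dark_wake_increase * wake_cyc else 0
            wake <- b$pct_wake + pct_int + wake_shift + stats::rnorm(1, 0, 2.5)
            # REM continuity: constant run-entry flow with geometric run
            # lengths at continuation rem_p, so fragmentation shortens and
            # de-qualifies episodes (fewer, shorter bouts) while run starts
            # persist
            rem_p <- b$rem_continuation *
              tr$rem_fragmentation_rate^cyc
            runs_frac <- b$pct_rem / 100 * (1 - b$rem_continuation)
            rem_pct <- max(100 * runs_frac / (1 - rem_p) *
                             (0.9 + 0.2 * stats::runif(1)), 0.5)
            nrem <- 100 - wake - rem_pct
            if (nrem < 1) { nrem <- 1; wake <- 100 - nrem - rem_pct }
            n_rem_ep <- rem_pct / 100 * 12 * 3600 / cohort$epoch_seconds
            runs <- n_rem_ep * (1 - rem_p)
            rem_bouts <- runs * rem_p              # runs of length >= 2
            rem_len <- (2 + rem_p / (1 - rem_p)) * cohort$epoch_seconds
            sleep_bouts <- stats::rlnorm(1, log(60), 0.12)
            sleep_len <- stats::rlnorm(1, log(180), 0.10)
            mot <- base$motion[[ph]] *
              (if (dark) (1 + tr$motion_increase)^cyc else 1) *
              stats::rlnorm(1, 0, 0.12)
            pw <- b$band_power * scale2 * pow_int *
              stats::rlnorm(4, 0, 0.10)
            vals <- c(pct_wake = wake, pct_nrem = nrem, pct_rem = rem_pct,
                      power_delta = unname(pw["delta"]),
                      power_theta = unname(pw["theta"]),
                      power_alpha = unname(pw["alpha"]),
                      power_beta = unname(pw["beta"]),
                      power_total = unname(sum(pw)),
                      rem_bout_count = rem_bouts * stats::rlnorm(1, 0, 0.08),
                      rem_bout_mean_len_s = rem_len * stats::rlnorm(1, 0, 0.05),
                      sleep_bout_count = sleep_bouts,
                      sleep_bout_mean_len_s = sleep_len,
                      motion = unname(mot))
            rows[[length(rows) + 1L]] <- data.frame(
              animal_id = id, group = g, age_week = w, photoperiod = ph,
              outcome = names(vals), value = unname(vals),
              stringsAsFactors = FALSE)
            if (dark && w == max(ages)) sev <- nrem  # final dark NREM%
          }
          if (hypnogram_hours > 0 || signal_hours > 0) {
            mats <- default_transition_matrices()
            if (tr$dark_wake_increase > 0 && wake_cyc > 0) {
              mats$dark <- increase_wake_fraction(
                mats$dark, tr$dark_wake_increase * wake_cyc)
            }
            if (tr$rem_fragmentation_rate < 1 && cyc > 0) {
              m <- tr$rem_fragmentation_rate^cyc
              mats$light <- fragment_rem(mats$light, m)
              mats$dark <- fragment_rem(mats$dark, m)
            }
            hseed <- sample.int(.Machine$integer.max, 1L)
            hy <- simulate_hypnogram(photoperiod_schedule(), mats,
                                     duration_hours = max(hypnogram_hours,
                                                          signal_hours),
                                     epoch_seconds = cohort$epoch_seconds,
                                     seed = hseed)
            hyps[[id]][[as.character(w)]] <- hy
            if (signal_hours > 0) {
              n_ep <- as.integer(signal_hours * 3600 / cohort$epoch_seconds)
              hy_sig <- new_hypnogram(hy$labels[seq_len(n_ep)],
                                      hy$epoch_seconds, hy$start_clock_time,
                                      hy$schedule)
              recs[[id]][[as.character(w)]] <- synthesize_signals(
                hy_sig, state_spectrum_specs(amplitude_scale = sqrt(scale2)),
                fs = cohort$fs, seed = hseed + 1L,
                animal_id = id, group = g, age_week = w)
            }
          }
        }
        atr[[length(atr) + 1L]] <- data.frame(
          animal_id = id, group = g, severity_raw = sev,
          stringsAsFactors = FALSE)
      }
    }
    metrics <- do.call(rbind, rows)
    atrophy <- do.call(rbind, atr)
    # thickness: group mean + coupling * within-group standardised severity
    atrophy$thickness_mm <- NA_real_
    for (g in groups) {
      i <- atrophy$group == g
      z <- scale(atrophy$severity_raw[i])
      if (any(!is.finite(z))) z <- rep(0, sum(i))
      p <- link[[g]]
      atrophy$thickness_mm[i] <- p[["mean_mm"]] +
        coupling * p[["sd_mm"]] * as.numeric(z) +
        stats::rnorm(sum(i), 0, p[["sd_mm"]] * sqrt(max(0, 1 - coupling^2)))
    }
    atrophy$severity_raw <- NULL
    out <- list(metrics = metrics, atrophy = atrophy)
    if (hypnogram_hours > 0 || signal_hours > 0) out$hypnograms <- hyps
    if (signal_hours > 0) out$recordings <- recs
    out
  })
  structure(res, class = "study_dataset")
}

#' Synthesize greyscale home-cage video frames
#'
#' Produces a sequence of 8-bit greyscale frames over a static background.
#' Frame `t` shows a moving dark block whose area tracks
#' `motion_trace[t]`, so the number of pixels changed from the previous
#' frame is monotone in the trace; zero intensity copies the previous frame
#' exactly.
#'
#' @param motion_trace non-negative per-frame activity intensities
#'   (approximate changed-pixel budget).
#' @param frame_shape `c(height, width)` in pixels (default 480 x 720).
#' @param seed integer seed (background texture).
#' @param block_grey_delta grey-level offset of the moving block above the
#'   local background (>= 10 so motion clears the compression threshold).
#' @return list of integer matrices (grey 0-255), one per frame.
#' @export
synthesize_video <- function(motion_trace, frame_shape = c(480, 720),
                             seed = 1, block_grey_delta = 60) {
  abort_if(any(motion_trace < 0), "motion intensities must be >= 0")
  h <- frame_shape[1]; w <- frame_shape[2]
  with_seed(seed, {
    bg <- matrix(as.integer(pmin(pmax(round(stats::rnorm(h * w, 120, 8)), 0),
                                 200)), h, w)
    frames <- vector("list", length(motion_trace))
    prev <- bg
    for (t in seq_along(motion_trace)) {
      I <- motion_trace[t]
      if (I == 0) {
        frames[[t]] <- prev
        next
      }
      side <- min(ceiling(sqrt(I)), min(h, w) %/% 3)
      fr <- bg
      # block alternates between two home-cage corners as the animal moves
      r0 <- if (t %% 2 == 0) h %/% 4 else (2 * h) %/% 3
      c0 <- if (t %% 2 == 0) w %/% 4 else (2 * w) %/% 3
      rows <- r0:(r0 + side - 1)
      cols <- c0:(c0 + side - 1)
      fr[rows, cols] <- pmin(fr[rows, cols] + as.integer(block_grey_delta),
                             255L)
      frames[[t]] <- fr
      prev <- fr
    }
    frames
  })
}
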