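## Arousal-state staging: per-animal state templates (seeded or
## unsupervised), ranked-membership classification with EMG criteria.

#' Fit per-animal state templates
#'
#' Builds individually optimised state templates from one week's epoch
#' features. In labelled mode the centroids are per-state means of the
#' standardised seed features. In unsupervised mode, k-means (20 restarts,
#' deterministic seed) partitions the standardised features and clusters are
#' assigned semantically: the highest-delta-power cluster is NREM; of the
#' rest, the lowest-EMG cluster is REM (atonia); of the remaining two, the
#' lower theta/delta ratio is WAKE and the other THETA_WAKE. EMG thresholds
#' sit at midpoints between state-wise EMG RMS medians: atonia between REM
#' and NREM, wake between NREM and WAKE.
#'
#' @param features data.frame from [extract_features()]; artefact rows are
#'   dropped.
#' @param labels optional character vector (same length as rows of
#'   `features`) of seed labels over `arousal_states()`; `NA` for unlabelled
#'   epochs. When supplied, labelled mode is used.
#' @param seed integer seed for the k-means restarts.
#' @return object of class `state_templates`: list with `centroids`
#'   (state x feature matrix, standardised), `centre`, `spread` (per-feature
#'   standardisation), `emg_atonia_threshold`, `emg_wake_threshold`,
#'   `feature_names`, `animal_id`, `mode`.
#' @export
fit_templates <- function(features, labels = NULL, seed = 1) {
  cols <- staging_feature_columns()
  keep <- !features$artefact
  X <- as.matrix(features[keep, cols])
  X[is.na(X)] <- 0
  abort_if(nrow(X) < 50, "need at least 50 non-artefact epochs")
  centre <- colMeans(X)
  spread <- apply(X, 2, stats::sd)
  spread[spread < .Machine$double.eps] <- 1
  Z <- scale(X, center = centre, scale = spread)

  st <- arousal_states()
  if (!is.null(labels)) {
    lab <- labels[keep]
    abort_if(!all(stats::na.omit(lab) %in% st),
             "seed labels must be arousal states")
    counts <- table(factor(lab, levels = st))
    abort_if(any(counts < 5), "need >= 5 seed epochs per state")
    centroids <- t(sapply(st, function(s) colMeans(Z[which(lab == s), ,
                                                     drop = FALSE])))
    assign_idx <- lapply(st, function(s) which(lab == s))
    names(assign_idx) <- st
    mode <- "seeded"
  } else {
    km <- NULL
    for (attempt in seq_len(20)) {
      km <- try(with_seed(seed + attempt - 1L,
                          stats::kmeans(Z, centers = 4, nstart = 20,
                                        iter.max = 100)),
                silent = TRUE)
      if (!inherits(km, "try-error") && all(km$size > 0)) break
      km <- NULL
    }
    abort_if(is.null(km),
             "degenerate clustering: could not form 4 non-empty clusters")
    # semantic assignment on the raw (unstandardised) scale
    raw_cent <- t(sapply(seq_len(4), function(k) {
      colMeans(X[km$cluster == k, , drop = FALSE])
    }))
    remaining <- seq_len(4)
    nrem <- remaining[which.max(raw_cent[remaining, "power_delta"])]
    remaining <- setdiff(remaining, nrem)
    rem <- remaining[which.min(raw_cent[remaining, "emg_rms"])]
    remaining <- setdiff(remaining, rem)
    ratio <- raw_cent[remaining, "power_theta"] /
      pmax(raw_cent[remaining, "power_delta"], .Machine$double.eps)
    wake <- remaining[which.min(ratio)]
    theta_wake <- setdiff(remaining, wake)
    ord <- c(WAKE = wake, THETA_WAKE = theta_wake, NREM = nrem, REM = rem)
    centroids <- km$centers[ord, , drop = FALSE]
    rownames(centroids) <- st
    assign_idx <- lapply(ord, function(k) which(km$cluster == k))
    names(assign_idx) <- st
    mode <- "unsupervised"
  }
  emg_med <- vapply(st, function(s) {
    stats::median(X[assign_idx[[s]], "emg_rms"])
  }, numeric(1))
  atonia <- (emg_med["REM"] + emg_med["NREM"]) / 2
  wake_thr <- (emg_med["NREM"] + emg_med["WAKE"]) / 2
  if (atonia >= wake_thr) atonia <- 0.99 * wake_thr
  d <- stats::dist(centroids)
  abort_if(any(d < 1e-12), "state centroids are not distinct")
  structure(list(centroids = centroids, centre = centre, spread = spread,
                 emg_atonia_threshold = unname(atonia),
                 emg_wake_threshold = unname(wake_thr),
                 feature_names = cols,
                 animal_id = features$animal_id[1] %||% NA_character_,
                 mode = mode),
            class = "state_templates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify epochs by ranked membership
#'
#' For every feature, the candidate states are ranked by the closeness of
#' the epoch's standardised value to each state centroid's value (rank 1 =
#' closest; ties get the minimum rank). The state with the smallest mean
#' rank wins; mean-rank ties break by smallest standardised Euclidean
#' distance to the centroid, then by the fixed order NREM, REM, THETA_WAKE,
#' WAKE. EMG overrides then apply: a REM call with EMG RMS above the atonia
#' threshold becomes THETA_WAKE; a WAKE/THETA_WAKE call with EMG below the
#' atonia threshold and theta power exceeding delta power becomes REM.
#'
#' @param features data.frame from [extract_features()] (or a single row).
#' @param templates a `state_templates`.
#' @param method `"rank"` (ranked membership, default) or `"distance"`
#'   (nearest standardised centroid, a plain fallback for comparison); the
#'   EMG overrides apply in both modes.
#' @return character vector of state labels, one per row.
#' @export
rank_membership_classify <- function(features, templates,
                                     method = c("rank", "distance")) {
  method <- match.arg(method)
  abort_if(any(features$artefact),
           "artefact epochs must be masked before classification")
  st <- arousal_states()
  tie_order <- c("NREM", "REM", "THETA_WAKE", "WAKE")
  cols <- templates$feature_names
  X <- as.matrix(features[, cols, drop = FALSE])
  X[is.na(X)] <- 0
  Z <- scale(X, center = templates$centre, scale = templates$spread)
  C <- templates$centroids[st, cols, drop = FALSE]
  n <- nrow(Z)
  out <- character(n)
  for (i in seq_len(n)) {
    d_feat <- abs(matrix(Z[i, ], nrow = 4, ncol = length(cols),
                         byrow = TRUE) - C)
    if (method == "rank") {
      ranks <- apply(d_feat, 2, rank, ties.method = "min")
      score <- rowMeans(ranks)
    } else {
      score <- rowSums(d_feat^2)
    }
    best <- which(score == min(score))
    if (length(best) > 1) {
      dist2 <- rowSums(d_feat[best, , drop = FALSE]^2)
      best <- best[dist2 == min(dist2)]
      if (length(best) > 1) {
        best <- best[order(match(st[best], tie_order))][1]
      }
    }
    lab <- st[best[1]]
    emg <- X[i, "emg_rms"]
    if (lab == "REM" && emg > templates$emg_atonia_threshold) {
      lab <- "THETA_WAKE"
    } else if (lab %in% c("WAKE", "THETA_WAKE") &&
               emg < templates$emg_atonia_threshold &&
               X[i, "power_theta"] > X[i, "power_delta"]) {
      lab <- "REM"
    }
    out[i] <- lab
  }
  out
}

#' Score a recording into a hypnogram
#'
#' Extracts features, applies epoch-level quality control, classifies every
#' clean epoch by ranked membership and labels artefact epochs `ARTEFACT`.
#' Deterministic given the recording and templates; no temporal smoothing
#' is applied by default (on-line per-epoch scoring). An optional 3-epoch
#' majority filter is available.
#'
#' @param recording a `recording`.
#' @param templates a `state_templates` (fit on the same animal-week).
#' @param features optional precomputed [extract_features()] output.
#' @param artefact_mask optional logical per-epoch mask; when missing, the
#'   package's clipping/flat-line detectors are run.
#' @param smooth if `TRUE`, apply a 3-epoch majority filter (default off).
#' @return a `hypnogram` with per-epoch labels.
#' @export
score_recording <- function(recording, templates, features = NULL,
                            artefact_mask = NULL, smooth = FALSE) {
  if (is.null(features)) features <- extract_features(recording)
  if (is.null(artefact_mask)) {
    artefact_mask <- qc_epoch_flags(recording)$flag
  }
  n <- nrow(features)
  abort_if(length(artefact_mask) != n,
           "artefact mask length must match epoch count")
  labels <- rep("ARTEFACT", n)
  clean <- !artefact_mask
  if (any(clean)) {
    feats <- features[clean, , drop = FALSE]
    feats$artefact <- FALSE
    labels[clean] <- rank_membership_classify(feats, templates)
  }
  if (smooth && n >= 3) {
    sm <- labels
    for (i in 2:(n - 1)) {
      tri <- labels[(i - 1):(i + 1)]
      if (any(tri == "ARTEFACT")) next
      tab <- table(tri)
      if (max(tab) >= 2) sm[i] <- names(tab)[which.max(tab)]
    }
    labels <- sm
  }
  new_hypnogram(labels, epoch_seconds = features$epoch_seconds %||% 10,
                start_clock_time = recording$start_clock_time,
                schedule = recording$schedule)
}
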