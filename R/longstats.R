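## Longitudinal group statistics: least-squares (cell) means under a
## group x age repeated-measures layout with unstructured within-animal
## covariance, Tukey-Kramer pairwise contrasts with optional log-scale
## back-transform, terminal one-way ANOVA with Tukey HSD, and
## actual/residual Spearman correlation against terminal atrophy.

#' Fit the repeated-measures group x age model
#'
#' Cell-means (profile) estimation: the least-squares mean of every
#' group x age cell is its arithmetic mean (on the log scale when
#' requested), and the within-animal covariance across ages is estimated
#' unstructured from residual cross-products, pooled over groups, with
#' pairwise-complete handling of missing weeks. Deterministic — no
#' iterative likelihood.
#'
#' @param table long data.frame with columns `animal_id`, `group`,
#'   `age_week`, `outcome`, `value` (optionally `photoperiod`; filter
#'   before fitting).
#' @param outcome outcome name to fit.
#' @param log_scale analyse on the natural-log scale (requires strictly
#'   positive values); contrasts then back-transform to ratios.
#' @param block optional additive blocking factor (e.g. recording
#'   location), one level per row of `table`: per age, block-mean
#'   deviations are removed from the values before the cell-means fit.
#' @return object of class `rm_fit`: list with `lsmeans` (group x age
#'   matrix), `cov` (age x age unstructured estimate), `n` (group x age
#'   cell counts), `groups`, `ages`, `scale`, `outcome`.
#' @export
fit_repeated_measures <- function(table, outcome, log_scale = FALSE,
                                  block = NULL) {
  if (!is.null(block)) table$.block <- factor(block)
  d <- table[table$outcome == outcome, , drop = FALSE]
  abort_if(nrow(d) == 0, sprintf("no rows for outcome '%s'", outcome))
  groups <- sort(unique(d$group))
  ages <- sort(unique(d$age_week))
  abort_if(length(groups) < 2 || length(ages) < 1,
           "need >= 2 groups and >= 1 age")
  if (log_scale) {
    abort_if(any(d$value <= 0, na.rm = TRUE),
             "log-scale analysis requires strictly positive values")
    d$value <- log(d$value)
  }
  if (!is.null(block)) {
    for (a in unique(d$age_week)) {
      i <- d$age_week == a
      dev <- stats::ave(d$value[i], d$.block[i]) - mean(d$value[i])
      d$value[i] <- d$value[i] - dev
    }
  }
  # animal x age wide matrix per group
  wide <- list()
  for (g in groups) {
    dg <- d[d$group == g, ]
    animals <- unique(dg$animal_id)
    M <- matrix(NA_real_, length(animals), length(ages),
                dimnames = list(animals, as.character(ages)))
    M[cbind(match(dg$animal_id, animals), match(dg$age_week, ages))] <-
      dg$value
    wide[[g]] <- M
  }
  lsmeans <- matrix(NA_real_, length(groups), length(ages),
                    dimnames = list(groups, as.character(ages)))
  ncell <- matrix(0L, length(groups), length(ages),
                  dimnames = dimnames(lsmeans))
  for (g in groups) {
    lsmeans[g, ] <- colMeans(wide[[g]], na.rm = TRUE)
    ncell[g, ] <- colSums(!is.na(wide[[g]]))
  }
  abort_if(any(ncell == 0),
           "every group x age cell needs at least one observation")

  # pooled unstructured covariance from residuals, pairwise complete
  A <- length(ages)
  S <- matrix(NA_real_, A, A, dimnames = list(colnames(lsmeans),
                                              colnames(lsmeans)))
  resid <- do.call(rbind, lapply(groups, function(g) {
    sweep(wide[[g]], 2, lsmeans[g, ])
  }))
  G <- length(groups)
  for (j in seq_len(A)) {
    for (k in j:A) {
      ok <- !is.na(resid[, j]) & !is.na(resid[, k])
      nn <- sum(ok)
      abort_if(nn <= G, "too few complete pairs to estimate covariance")
      S[j, k] <- S[k, j] <- sum(resid[ok, j] * resid[ok, k]) / (nn - G)
    }
  }
  structure(list(lsmeans = lsmeans, cov = S, n = ncell, groups = groups,
                 ages = ages, scale = if (log_scale) "log" else "raw",
                 outcome = outcome),
            class = "rm_fit")
}

#' All pairwise group contrasts at every age, Tukey-Kramer adjusted
#'
#' Every group pair at every age: the estimate is the difference of
#' least-squares means, the standard error uses the unstructured
#' covariance's diagonal with Kramer's unequal-n correction, and the
#' adjusted p comes from the studentized-range distribution for the number
#' of groups. By default each age is one simultaneous family (the
#' per-timepoint reading of the published 6-pairs x 7-ages = 42
#' comparisons); `family = "global"` additionally Bonferroni-corrects
#' across ages.
#'
#' @param fit an `rm_fit`.
#' @param alpha significance level (default 0.05).
#' @param family `"per_age"` (default) or `"global"`.
#' @return data.frame of class `contrast_table`: one row per pair x age
#'   with `group1`, `group2`, `age_week`, `estimate`, `se`, `df`,
#'   `p_unadj`, `p_adj`, `significant`, and for log-scale fits `ratio`,
#'   `ratio_lo`, `ratio_hi`.
#' @export
pairwise_contrasts <- function(fit, alpha = 0.05,
                               family = c("per_age", "global")) {
  family <- match.arg(family)
  groups <- fit$groups
  ages <- fit$ages
  G <- length(groups)
  pairs <- utils::combn(groups, 2)
  rows <- list()
  for (a in seq_along(ages)) {
    s2 <- fit$cov[a, a]
    if (!is.finite(s2) || s2 <= 0) {
      warning(sprintf("non-positive variance at age %s; contrasts skipped",
                      ages[a]))
      next
    }
    n_a <- fit$n[, a]
    df <- sum(n_a) - G
    for (p in seq_len(ncol(pairs))) {
      g1 <- pairs[1, p]; g2 <- pairs[2, p]
      est <- fit$lsmeans[g1, a] - fit$lsmeans[g2, a]
      se <- sqrt(s2 * (1 / n_a[g1] + 1 / n_a[g2]))   # Kramer adjustment
      tval <- est / se
      p_un <- 2 * stats::pt(-abs(tval), df)
      p_ad <- stats::ptukey(sqrt(2) * abs(tval), nmeans = G, df = df,
                            lower.tail = FALSE)
      if (family == "global") p_ad <- min(1, p_ad * length(ages))
      row <- data.frame(group1 = g1, group2 = g2, age_week = ages[a],
                        estimate = unname(est), se = unname(se), df = df,
                        p_unadj = unname(p_un), p_adj = unname(p_ad),
                        significant = unname(p_ad < alpha),
                        stringsAsFactors = FALSE)
      if (fit$scale == "log") {
        crit <- stats::qtukey(1 - alpha, nmeans = G, df = df) / sqrt(2)
        row$ratio <- exp(row$estimate)
        row$ratio_lo <- exp(row$estimate - crit * row$se)
        row$ratio_hi <- exp(row$estimate + crit * row$se)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "scale") <- fit$scale
  attr(res, "family_size") <- ncol(pairs) * length(ages)
  class(res) <- c("contrast_table", class(res))
  res
}

#' Back-transform log-scale contrasts to multiplicative ratios
#'
#' Exponentiates log-scale differences and their interval endpoints, so a
#' difference of 0 maps to a ratio of 1 and group effects read as
#' multiplicative changes.
#'
#' @param contrasts a `contrast_table` from a log-scale fit.
#' @return the table with `ratio`, `ratio_lo`, `ratio_hi` columns.
#' @export
back_transform <- function(contrasts) {
  abort_if(!identical(attr(contrasts, "scale"), "log"),
           "back_transform applies only to log-scale contrasts")
  if (!"ratio" %in% names(contrasts)) {
    contrasts$ratio <- exp(contrasts$estimate)
  }
  contrasts
}

#' One-way ANOVA with Tukey post hoc test on terminal measures
#'
#' Classical one-way F (via `stats::aov`) with Tukey honest significant
#' differences (Kramer-adjusted for unequal n) on the group pairs.
#'
#' @param values numeric terminal measurements.
#' @param group factor/character group labels.
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `posthoc` (data.frame: pair, diff, lo, hi, p_adj).
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  abort_if(nlevels(group) < 2, "need >= 2 groups")
  abort_if(any(table(group) < 2), "need >= 2 values per group")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  abort_if(!is.finite(tab$`F value`[1]),
           "F undefined: no within-group variance")
  tk <- stats::TukeyHSD(fit)$group
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lo = tk[, "lwr"], hi = tk[, "upr"],
                        p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(posthoc) <- NULL
  structure(list(F = tab$`F value`[1], df_between = tab$Df[1],
                 df_within = tab$Df[2], p = tab$`Pr(>F)`[1],
                 posthoc = posthoc),
            class = "anova_result")
}

#' Spearman correlation of a final outcome with terminal atrophy
#'
#' `mode = "actual"` correlates the raw pairs pooled across groups — this
#' picks up group-mean separation as well as within-group association.
#' `mode = "residual"` centres both variables by their group means first,
#' isolating the within-group association. p values use the
#' t-approximation, or the exact null distribution for n < 12 (when there
#' are no ties).
#'
#' @param outcome per-animal final (dark-period) outcome values.
#' @param atrophy per-animal terminal thickness values, same order.
#' @param group group labels (required for residual mode).
#' @param mode `"actual"` or `"residual"`.
#' @return list of class `correlation_result`: `rs`, `p`, `n`, `mode`,
#'   `degenerate` (TRUE when a variable had no variance).
#' @export
correlate_with_atrophy <- function(outcome, atrophy, group = NULL,
                                   mode = c("actual", "residual")) {
  mode <- match.arg(mode)
  ok <- is.finite(outcome) & is.finite(atrophy)
  x <- outcome[ok]; y <- atrophy[ok]
  abort_if(length(x) < 5, "need >= 5 paired observations")
  if (mode == "residual") {
    abort_if(is.null(group), "residual mode requires group labels")
    g <- factor(group[ok])
    x <- x - stats::ave(x, g)
    y <- y - stats::ave(y, g)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(rs = NA_real_, p = NA_real_, n = length(x),
                          mode = mode, degenerate = TRUE),
                     class = "correlation_result"))
  }
  exact <- length(x) < 12 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  structure(list(rs = unname(ct$estimate), p = ct$p.value, n = length(x),
                 mode = mode, degenerate = FALSE),
            class = "correlation_result")
}
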