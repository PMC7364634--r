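# Build a long-format table for a balanced multivariate-normal design.
make_table <- function(groups, ages, n, mu = NULL, Sigma = NULL,
                       outcome = "y") {
  A <- length(ages)
  if (is.null(Sigma)) Sigma <- diag(A)
  L <- chol(Sigma)
  rows <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(n)) {
      m <- if (is.null(mu)) rep(0, A) else mu[g, ]
      y <- m + as.numeric(matrix(rnorm(A), 1) %*% L)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = paste0(groups[g], "_", i), group = groups[g],
        age_week = ages, outcome = outcome, value = y,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("LS means equal arithmetic cell means under balance and the covariance is recovered", {
  set.seed(401)
  groups <- c("WT", "Tg")
  ages <- c(20, 24, 28)
  tab <- make_table(groups, ages, 8)
  fit <- fit_repeated_measures(tab, "y")
  for (g in groups) for (a in ages) {
    cell <- tab$value[tab$group == g & tab$age_week == a]
    expect_equal(fit$lsmeans[g, as.character(a)], mean(cell))
  }
  # compound-symmetric truth rho = 0.5: off-diagonals recovered within 0.1
  Sigma <- 0.5 * diag(3) + 0.5
  tab2 <- make_table(c("WT", "tTA", "Tg", "TgDOX"), ages, 50, Sigma = Sigma)
  fit2 <- fit_repeated_measures(tab2, "y")
  off <- abs(fit2$cov - Sigma)[upper.tri(Sigma)]
  expect_lt(mean(off), 0.1)

  expect_error(fit_repeated_measures(transform(tab, value = value - 10),
                                     "y", log_scale = TRUE), "positive")
})

test_that("cell means and pooled variances agree with a gls/emmeans reference fit", {
  skip_if_not_installed("nlme")
  skip_if_not_installed("emmeans")
  set.seed(402)
  tab <- make_table(c("WT", "tTA", "Tg"), c(20, 24), 10,
                    Sigma = matrix(c(1, .4, .4, 1), 2))
  fit <- fit_repeated_measures(tab, "y")
  ref <- nlme::gls(value ~ group * factor(age_week), data = tab,
                   correlation = nlme::corSymm(form = ~1 | animal_id),
                   weights = nlme::varIdent(form = ~1 | age_week))
  em <- suppressMessages(
    as.data.frame(emmeans::emmeans(ref, ~ group | age_week, data = tab)))
  for (r in seq_len(nrow(em))) {
    expect_equal(fit$lsmeans[as.character(em$group[r]),
                             as.character(em$age_week[r])],
                 em$emmean[r], tolerance = 1e-3)
  }
})

test_that("pairwise contrasts enumerate C(G,2) x A and adjust p upwards, monotonically", {
  set.seed(403)
  tab <- make_table(c("WT", "tTA", "Tg", "TgDOX"), seq(20, 44, 4), 6)
  fit <- fit_repeated_measures(tab, "y")
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), choose(4, 2) * 7)
  expect_equal(attr(ct, "family_size"), 42)
  expect_true(all(ct$p_adj >= ct$p_unadj - 1e-12))
  # adjusted p monotone in unadjusted p within each family
  for (a in unique(ct$age_week)) {
    fam <- ct[ct$age_week == a, ]
    o <- order(fam$p_unadj)
    expect_true(all(diff(fam$p_adj[o]) >= -1e-12))
  }

  # 2 groups x 1 age: Tukey with k = 2 equals the unadjusted t test
  tab2 <- make_table(c("A", "B"), 20, 8)
  ct2 <- pairwise_contrasts(fit_repeated_measures(tab2, "y"))
  expect_equal(nrow(ct2), 1)
  expect_equal(ct2$p_adj, ct2$p_unadj, tolerance = 1e-9)
})

test_that("Tukey-Kramer adjusted p values match multcomp on a terminal one-way layout", {
  skip_if_not_installed("multcomp")
  set.seed(404)
  tab <- make_table(c("WT", "tTA", "Tg", "TgDOX"), 44, 9)
  fit <- fit_repeated_measures(tab, "y")
  ct <- pairwise_contrasts(fit)
  d <- tab
  d$group <- factor(d$group)
  ref <- summary(multcomp::glht(stats::aov(value ~ group, data = d),
                                linfct = multcomp::mcp(group = "Tukey")),
                 test = multcomp::adjusted("single-step"))
  expect_equal(sort(ct$p_adj), sort(as.numeric(ref$test$pvalues)),
               tolerance = 0.02)
})

test_that("log-scale fits back-transform to the injected multiplicative effect", {
  set.seed(405)
  groups <- c("A", "B")
  ages <- 20
  mu <- matrix(c(log(10), log(15)), 2, 1)   # geometric means differ x1.5
  tab <- make_table(groups, ages, 200, mu = mu, Sigma = matrix(0.04))
  tab$value <- exp(tab$value)
  fit <- fit_repeated_measures(tab, "y", log_scale = TRUE)
  ct <- pairwise_contrasts(fit)
  expect_equal(ct$ratio, 10 / 15, tolerance = 0.05)

  # closed-form identities and the exp/log round trip
  expect_equal(back_transform(ct)$ratio, exp(ct$estimate), tolerance = 1e-12)
  raw <- pairwise_contrasts(fit_repeated_measures(
    transform(tab, value = log(value)), "y"))
  expect_equal(exp(raw$estimate), ct$ratio, tolerance = 1e-12)
  expect_error(back_transform(raw), "log")

  # x0.8 effect recovered at n = 20
  mu2 <- matrix(c(log(10), log(8)), 2, 1)
  tab2 <- make_table(groups, ages, 20, mu = mu2, Sigma = matrix(0.01))
  tab2$value <- exp(tab2$value)
  ct2 <- pairwise_contrasts(fit_repeated_measures(tab2, "y",
                                                  log_scale = TRUE))
  expect_equal(ct2$ratio, 10 / 8, tolerance = 0.07)
})

test_that("one-way ANOVA matches classical identities", {
  set.seed(406)
  # identical group means: F ~ 0 on noiseless shifted data
  v <- rep(c(1, 2, 3), 4)
  g <- rep(c("a", "b"), each = 6)
  res <- one_way_anova(v, g)
  expect_lt(res$F, 1e-20)
  expect_true(all(res$posthoc$p_adj > 0.99))

  # 2 groups: F equals the squared equal-variance t statistic
  x <- rnorm(10); y <- rnorm(12, 1)
  res2 <- one_way_anova(c(x, y), rep(c("a", "b"), c(10, 12)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$df_between, 1)
  expect_equal(res2$df_within, 20)

  expect_error(one_way_anova(1:3, c("a", "a", "b")), "2 values")
})

test_that("empirical ANOVA power tracks the noncentral-F closed form", {
  set.seed(407)
  groups <- 4; n <- 8
  means <- c(0, 0.4, 0.8, 1.2)
  lambda <- n * sum((means - mean(means))^2)     # noncentrality, sigma = 1
  crit <- qf(0.95, groups - 1, groups * (n - 1))
  power_cf <- 1 - pf(crit, groups - 1, groups * (n - 1), ncp = lambda)
  hits <- replicate(1000, {
    v <- rnorm(groups * n, rep(means, each = n))
    one_way_anova(v, rep(letters[1:groups], each = n))$p < 0.05
  })
  expect_equal(mean(hits), power_cf, tolerance = 0.03)
})

test_that("actual and residual Spearman correlations behave as designed", {
  set.seed(408)
  g <- rep(c("a", "b", "c"), each = 10)
  x <- rnorm(30) + rep(c(0, 2, 4), each = 10)
  # y increasing in x within every group (common slope): residual rs = 1
  y <- rep(c(10, 0, -10), each = 10) + 2 * x
  res <- correlate_with_atrophy(x, y, g, mode = "residual")
  expect_equal(res$rs, 1)

  # constant variable flags degenerate
  res0 <- correlate_with_atrophy(rep(1, 10), rnorm(10),
                                 rep("a", 10), mode = "actual")
  expect_true(res0$degenerate)

  # small-sample p agrees with the exact null distribution
  xs <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  ys <- c(2, 7, 1.8, 2.8, 1.2, 8.9, 7.9)
  res_small <- correlate_with_atrophy(xs, ys, mode = "actual")
  ref <- cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(res_small$p, ref$p.value)
})

test_that("group-shift-only data dissociate actual from residual correlation", {
  set.seed(409)
  reps <- 50
  actual <- numeric(reps); residual <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- rep(c("WT", "tTA", "Tg", "TgDOX"), each = 12)
    shift <- rep(c(0, 0.5, 3, 1), each = 12)
    x <- shift + rnorm(48, 0, 0.5)
    y <- -shift + rnorm(48, 0, 0.5)      # linked only through group means
    actual[r] <- abs(correlate_with_atrophy(x, y, mode = "actual")$rs)
    residual[r] <- abs(correlate_with_atrophy(x, y, g,
                                              mode = "residual")$rs)
  }
  expect_gt(mean(actual > 0.5), 0.9)
  expect_lt(mean(residual), 0.15)
})

test_that("an additive block factor is removed before the cell-means fit", {
  set.seed(410)
  tab <- make_table(c("A", "B"), c(20, 24), 8)
  blk <- rep(rep(c("site1", "site2"), each = 4 * 2), 2)[seq_len(nrow(tab))]
  shifted <- tab
  shifted$value <- shifted$value + ifelse(blk == "site2", 5, 0)
  fit_plain <- fit_repeated_measures(tab, "y")
  fit_block <- fit_repeated_measures(shifted, "y", block = blk)
  # block-adjusted contrasts match the unshifted data's contrasts
  ct_plain <- pairwise_contrasts(fit_plain)
  ct_block <- pairwise_contrasts(fit_block)
  expect_equal(ct_block$estimate, ct_plain$estimate, tolerance = 1e-9)
})
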