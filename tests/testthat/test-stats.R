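test_that("one-way ANOVA matches a hand computation on a small set", {
  set.seed(30)
  g <- rep(c("R", "P", "F"), each = 3)
  y <- c(1.2, 0.9, 1.4, 0.7, 0.8, 0.5, 0.3, 0.6, 0.2)
  res <- one_way_anova(y, g, "demo")
  # textbook decomposition with explicit sums
  grand <- sum(y) / 9
  ssb <- sum(vapply(unique(g), function(gr) {
    3 * (mean(y[g == gr]) - grand)^2
  }, numeric(1)))
  ssw <- sum(vapply(unique(g), function(gr) {
    sum((y[g == gr] - mean(y[g == gr]))^2)
  }, numeric(1)))
  F_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, F_oracle, tolerance = 1e-9)
  expect_equal(res$p, stats::pf(F_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$eta2p, ssb / (ssb + ssw), tolerance = 1e-9)
  expect_equal(unname(res$df), c(2, 6))
})

test_that("degenerate ANOVA cases behave as defined", {
  # zero within-group variance, different means
  res <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(res$eta2p, 1)
  # all observations equal
  res <- one_way_anova(rep(3, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 0)
  expect_equal(res$eta2p, 0)
  # group with a single observation
  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")), "at least 2")
})

test_that("eta squared is invariant under affine response transforms", {
  set.seed(31)
  y <- rnorm(27)
  g <- rep(c("R", "P", "F"), times = c(8, 13, 6))
  e1 <- one_way_anova(y, g)$eta2p
  e2 <- one_way_anova(3 * y + 7, g)$eta2p
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("Tukey post hoc matches an independent studentized-range oracle", {
  set.seed(32)
  y <- c(rnorm(8, 0), rnorm(13, 0.8), rnorm(6, 1.6))
  g <- rep(c("R", "P", "F"), times = c(8, 13, 6))
  res <- tukey_posthoc(y, g)
  # oracle: explicit MSE and Tukey-Kramer studentized range probability
  lv <- c("F", "P", "R")  # factor level order
  ns <- table(factor(g, levels = lv))
  ms <- tapply(y, factor(g, levels = lv), mean)
  mse <- sum(unlist(lapply(lv, function(l) (y[g == l] - ms[l])^2))) /
    (length(y) - 3)
  for (i in seq_len(nrow(res))) {
    ab <- strsplit(res$pair[i], "-")[[1]]
    se <- sqrt(mse / 2 * (1 / ns[ab[1]] + 1 / ns[ab[2]]))
    q <- abs(ms[ab[1]] - ms[ab[2]]) / se
    p_oracle <- stats::ptukey(q, nmeans = 3, df = length(y) - 3,
                              lower.tail = FALSE)
    expect_equal(res$p_adj[i], unname(p_oracle), tolerance = 1e-6)
    # Cohen's d against an explicit pooled-SD computation
    x1 <- y[g == ab[1]]; x2 <- y[g == ab[2]]
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                 (length(x1) + length(x2) - 2))
    expect_equal(res$cohen_d[i], (mean(x1) - mean(x2)) / sp,
                 tolerance = 1e-12)
  }
})

test_that("Tukey effect sizes behave at the boundaries", {
  # two groups exactly one pooled SD apart
  x <- c(1, 2, 3, 4, 5)
  y <- x + stats::sd(x)
  res <- tukey_posthoc(c(x, y), rep(c("a", "b"), each = 5))
  expect_equal(abs(res$cohen_d), 1, tolerance = 1e-12)
  # identical groups: adjusted p near 1
  res <- tukey_posthoc(c(x, x), rep(c("a", "b"), each = 5))
  expect_gt(res$p_adj, 0.999)
})

test_that("the permutation multivariate test validates inputs and detects effects", {
  set.seed(33)
  Y <- matrix(rnorm(27 * 9), 27, 9)
  g <- rep(c("R", "P", "F"), times = c(8, 13, 6))
  expect_error(multivariate_group_test(Y, g, n_perm = 0), "at least 1")
  expect_warning(multivariate_group_test(Y, g, n_perm = 50, seed = 1),
                 "coarse")
  # reproducible under seed
  a <- multivariate_group_test(Y, g, n_perm = 500, seed = 7)
  b <- multivariate_group_test(Y, g, n_perm = 500, seed = 7)
  expect_identical(a, b)
  # a strong effect on three parameters is detected
  Yeff <- Y
  shift <- (g == "R") * 2
  Yeff[, 1:3] <- Yeff[, 1:3] + shift
  res <- multivariate_group_test(Yeff, g, n_perm = 2000, seed = 5)
  expect_lt(res$p, 0.01)
})

test_that("fast column F statistics agree with aov", {
  set.seed(34)
  Y <- matrix(rnorm(27 * 4), 27, 4)
  g <- factor(rep(c("R", "P", "F"), times = c(8, 13, 6)))
  fast <- adlkin:::column_f_stats(Y, g)
  slow <- vapply(1:4, function(j) {
    summary(stats::aov(Y[, j] ~ g))[[1]]["g", "F value"]
  }, numeric(1))
  expect_equal(unname(fast), slow, tolerance = 1e-9)
})

test_that("the permutation test holds its level approximately under the null", {
  set.seed(35)
  g <- rep(c("R", "P", "F"), times = c(8, 13, 6))
  pvals <- vapply(seq_len(60), function(r) {
    Y <- matrix(rnorm(27 * 9), 27, 9)
    multivariate_group_test(Y, g, n_perm = 500, seed = 100 + r)$p
  }, numeric(1))
  # wide band at this replicate count; the tighter check runs in the
  # acceptance suite
  expect_lt(mean(pvals <= 0.05), 0.18)
  expect_gt(mean(pvals <= 0.5), 0.25)
})

test_that("inter-task correlation recovers exact and simulated relationships", {
  tabdf <- data.frame(x = c(1, 2, 3, 5, 8))
  expect_equal(inter_task_correlation(tabdf$x, y = tabdf$x)$r, 1)
  expect_equal(inter_task_correlation(tabdf$x, y = -tabdf$x)$r, -1)
  expect_warning(res <- inter_task_correlation(rep(1, 5), y = rnorm(5)),
                 "zero variance")
  expect_true(is.na(res$r))
  expect_error(inter_task_correlation(1:2, y = 1:2), "3 complete")
  # sampling behaviour at rho = 0.6, n = 27
  set.seed(36)
  rs <- vapply(seq_len(1000), function(r) {
    x <- rnorm(27)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(27)
    inter_task_correlation(x, y = y)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("stepwise regression recovers a dominant predictor", {
  set.seed(37)
  X <- matrix(rnorm(27 * 9), 27, 9)
  colnames(X) <- kinematic_parameters()
  y <- 2 * X[, "STD"] + rnorm(27, 0, 0.01)
  df <- data.frame(fried_score = y, X)
  m <- stepwise_mlr(df, response = "fried_score",
                    predictors = kinematic_parameters())
  expect_equal(m$selected[1], "STD")
  expect_gt(m$R2, 0.99)
  expect_true(all(m$vif < 5))
})

test_that("stepwise regression returns an empty model without signal", {
  set.seed(38)
  # response orthogonalized against all predictors: nothing can enter
  X <- matrix(rnorm(30 * 5), 30, 5)
  colnames(X) <- paste0("x", 1:5)
  y <- stats::resid(stats::lm(rnorm(30) ~ X))
  m <- stepwise_mlr(data.frame(fried_score = y, X),
                    response = "fried_score",
                    predictors = colnames(X))
  expect_length(m$selected, 0)
  expect_equal(m$R2, 0)
})

test_that("a frailty signal carried by STD yields a negative standardized beta", {
  cfg <- default_sim_config(seed = 12)
  coh <- simulate_cohort(cfg, c(R = 8, P = 13, F = 6))
  tab <- build_cohort_table(extract_cohort_features(coh))
  # plant the score as decreasing in averaged STD plus noise
  set.seed(39)
  tab$fried_score <- round(pmin(5, pmax(0,
    3 - 2.5 * scale(tab$STD_avg)[, 1] / 2 + rnorm(nrow(tab), 0, 0.4))))
  m <- stepwise_mlr(tab, scope = "avg")
  expect_true("STD_avg" %in% m$selected)
  expect_lt(m$beta_std[["STD_avg"]], 0)
})

test_that("collinear candidates are excluded by the VIF gate", {
  set.seed(40)
  x1 <- rnorm(40)
  x2 <- x1 + rnorm(40, 0, 0.01)  # VIF far above 5
  y <- x1 + x2 + rnorm(40, 0, 0.3)
  m <- stepwise_mlr(data.frame(fried_score = y, x1 = x1, x2 = x2),
                    response = "fried_score", predictors = c("x1", "x2"))
  expect_length(m$selected, 1)
  expect_true(all(m$vif < 5))
})

test_that("standardized betas and VIF agree with reference implementations", {
  skip_if_not_installed("car")
  set.seed(41)
  X <- matrix(rnorm(40 * 3), 40, 3)
  colnames(X) <- c("a", "b", "c")
  y <- X[, 1] - 0.8 * X[, 2] + rnorm(40, 0, 0.5)
  df <- data.frame(fried_score = y, X)
  m <- stepwise_mlr(df, response = "fried_score",
                    predictors = c("a", "b", "c"),
                    entry = 0.2)  # admit at least two predictors
  fit <- stats::lm(stats::reformulate(m$selected, "fried_score"), df)
  if (length(m$selected) >= 2) {
    expect_equal(unname(m$vif[m$selected]),
                 unname(car::vif(fit)[m$selected]), tolerance = 1e-9)
  }
  # standardized betas equal coefficients of the fully scaled fit
  dfs <- data.frame(scale(df[, c("fried_score", m$selected)]))
  fit_s <- stats::lm(stats::reformulate(m$selected, "fried_score"), dfs)
  expect_equal(unname(m$beta_std), unname(stats::coef(fit_s)[m$selected]),
               tolerance = 1e-9)
})

test_that("task averages merge the two ADL per participant", {
  feats <- data.frame(
    participant_id = rep(c("A", "B"), each = 2),
    task = rep(c("TEA", "GARDEN"), 2),
    group = "R", fried_score = 0,
    matrix(1, 4, 9, dimnames = list(NULL, kinematic_parameters())),
    stringsAsFactors = FALSE)
  feats$TD <- c(137, 96, 150, 117)
  tab <- build_cohort_table(feats)
  expect_equal(tab$TD_avg, c(116.5, 133.5))
  avg <- task_average(tab)
  expect_equal(avg$TD, c(116.5, 133.5))
  expect_equal(avg$RA, c(1, 1))  # equal values average to themselves
  # a participant missing one task is flagged and excluded
  feats2 <- feats[-2, ]
  tab2 <- build_cohort_table(feats2)
  expect_false(tab2$complete[tab2$participant_id == "A"])
  expect_true(is.na(tab2$TD_avg[tab2$participant_id == "A"]))
  expect_equal(task_average(tab2)$participant_id, "B")
})

test_that("duplicate participant x task rows are an error", {
  feats <- data.frame(
    participant_id = c("A", "A"), task = c("TEA", "TEA"),
    group = "R", fried_score = 0,
    matrix(1, 2, 9, dimnames = list(NULL, kinematic_parameters())),
    stringsAsFactors = FALSE)
  expect_error(build_cohort_table(feats), "duplicate")
})

test_that("pooled means weight subgroup means by size", {
  expect_equal(pooled_mean(c(2, 4), c(1, 3)), 3.5)
  expect_error(pooled_mean(c(1, 2), c(1, 0)))
})
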