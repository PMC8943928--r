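#' One-way ANOVA with partial eta squared
#'
#' Classical between/within one-way analysis of variance comparing a
#' kinematic parameter across frailty groups, with partial eta squared
#' (SS_between / (SS_between + SS_within)) as effect size. Missing values
#' are dropped (complete-case per comparison).
#'
#' @param values numeric vector of per-participant measurements.
#' @param groups group labels (coerced to factor).
#' @param parameter optional parameter name carried into the result.
#' @return list of class `group_comparison`: `parameter`, `F`, `df`
#'   (between, within), `p`, `eta2p`, and `posthoc` (`NULL`; see
#'   [tukey_posthoc()]).
#' @export
#' @examples
#' one_way_anova(c(1, 2, 5, 6, 9, 10), rep(c("R", "P", "F"), each = 2))
one_way_anova <- function(values, groups, parameter = NA_character_) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  g <- droplevels(factor(groups[ok]))
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need at least 2 groups with at least 2 observations each")
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab["g", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  Fv <- unname(tab["g", "F value"])
  pv <- unname(tab["g", "Pr(>F)"])
  eta <- ssb / (ssb + ssw)
  eps <- 1e-12 * max(1, sum(values^2))
  if (ssb + ssw <= eps) {        # constant response: no variance at all
    Fv <- 0; pv <- 1; eta <- 0
  } else if (ssw <= eps) {       # perfect separation within groups
    Fv <- Inf; pv <- 0; eta <- 1
  }
  structure(list(parameter = parameter,
                 F = Fv,
                 df = c(between = tab["g", "Df"],
                        within = tab["Residuals", "Df"]),
                 p = pv,
                 eta2p = eta,
                 posthoc = NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F(%d, %d) = %.3f, p = %.4f, eta2p = %.3f\n",
              x$parameter, x$df[1], x$df[2], x$F, x$p, x$eta2p))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' Tukey HSD post hoc comparisons with Cohen's d
#'
#' Pairwise Tukey honestly-significant-difference tests on the
#' studentized-range distribution, plus Cohen's d (pairwise mean
#' difference over the pooled standard deviation of the pair).
#'
#' @inheritParams one_way_anova
#' @return data frame with columns `pair`, `diff`, `p_adj`, `cohen_d`.
#' @export
tukey_posthoc <- function(values, groups) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  g <- droplevels(factor(groups[ok]))
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need at least 2 groups with at least 2 observations each")
  }
  hsd <- stats::TukeyHSD(stats::aov(values ~ g))$g
  pairs <- rownames(hsd)
  d <- vapply(pairs, function(pr) {
    ab <- strsplit(pr, "-", fixed = TRUE)[[1]]
    x1 <- values[g == ab[1]]
    x2 <- values[g == ab[2]]
    sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                  (length(x2) - 1) * stats::var(x2)) /
                 (length(x1) + length(x2) - 2))
    if (sp == 0) return(if (mean(x1) == mean(x2)) 0 else Inf)
    (mean(x1) - mean(x2)) / sp
  }, numeric(1))
  data.frame(pair = pairs, diff = unname(hsd[, "diff"]),
             p_adj = unname(hsd[, "p adj"]), cohen_d = unname(d),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare groups on one parameter (ANOVA + Tukey post hoc)
#'
#' @inheritParams one_way_anova
#' @return a `group_comparison` with the `posthoc` slot filled.
#' @export
compare_groups <- function(values, groups, parameter = NA_character_) {
  out <- one_way_anova(values, groups, parameter)
  out$posthoc <- tukey_posthoc(values, groups)
  out
}

# fast per-column one-way F statistics (used by the permutation test);
# columns with zero within-group variance get F = 0/Inf accordingly
column_f_stats <- function(Y, g) {
  n <- nrow(Y)
  k <- nlevels(g)
  cnt <- tabulate(g, k)
  gs <- rowsum(Y, g)
  gm <- gs / cnt
  grand <- colSums(Y) / n
  ssb <- colSums(cnt * (gm - matrix(grand, k, ncol(Y), byrow = TRUE))^2)
  sst <- colSums(Y^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  Fv[ssw == 0 & ssb == 0] <- 0
  Fv
}

#' Permutation multivariate group test
#'
#' Tests for any group effect across all kinematic parameters jointly.
#' The statistic is the sum of the per-parameter one-way F statistics
#' (each F is scale-free, so parameters on different scales contribute
#' comparably); its null distribution is obtained by permuting the group
#' labels, keeping each participant's parameter vector intact. The
#' p-value is the permutation tail probability with the add-one
#' correction (Phipson-Smyth).
#'
#' @param Y numeric matrix (participants x parameters) or a
#'   `cohort_table` (then `scope` selects the task columns).
#' @param groups group labels aligned with the rows of `Y`.
#' @param n_perm number of permutations (error if < 1; warning if < 100).
#' @param seed integer seed for the permutation stream.
#' @param scope when `Y` is a `cohort_table`: `"TEA"`, `"GARDEN"` or
#'   `"avg"` (task average).
#' @return list with `statistic`, `p`, and `n_perm`.
#' @export
multivariate_group_test <- function(Y, groups = NULL, n_perm = 10000,
                                    seed = 1L, scope = "avg") {
  if (inherits(Y, "cohort_table")) {
    tab <- Y[Y$complete, ]
    groups <- tab$group
    Y <- as.matrix(tab[, paste0(kinematic_parameters(), "_", scope)])
  }
  Y <- as.matrix(Y)
  ok <- stats::complete.cases(Y) & !is.na(groups)
  Y <- Y[ok, , drop = FALSE]
  g <- droplevels(factor(groups[ok]))
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse")
  obs <- sum(column_f_stats(Y, g))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      sum(column_f_stats(Y, g[sample.int(length(g))]))
    }, numeric(1)) >= obs)
  })
  list(statistic = obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Inter-task Pearson correlation of a parameter
#'
#' Correlates a kinematic parameter between the two ADL tasks (its TEA
#' value against its GARDEN value across participants), estimating the
#' task specificity / reliability of the measure.
#'
#' @param table a `cohort_table`, or a numeric vector (then `y` must be
#'   given).
#' @param parameter parameter name (when `table` is a `cohort_table`).
#' @param y second numeric vector when `table` is a vector.
#' @return list with `parameter`, `r`, `p`, and `n`. Zero variance in
#'   either task yields `r = NA` with a warning.
#' @export
inter_task_correlation <- function(table, parameter = NULL, y = NULL) {
  if (inherits(table, "cohort_table")) {
    x <- table[[paste0(parameter, "_TEA")]]
    y <- table[[paste0(parameter, "_GARDEN")]]
  } else {
    x <- table
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one task: correlation undefined")
    return(list(parameter = parameter, r = NA_real_, p = NA_real_,
                n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(parameter = parameter, r = unname(ct$estimate), p = ct$p.value,
       n = length(x))
}

#' Forward-stepwise multiple linear regression of the frailty score
#'
#' Models the adapted Fried score (0-5) from kinematic parameters by
#' forward-stepwise selection: at each step the candidate with the
#' smallest partial-F p-value enters if p <= `entry`, already-selected
#' predictors are removed again if their p-value rises to >= `removal`,
#' and a candidate whose entry would push any variance inflation factor
#' to `vif_limit` or above is skipped.
#'
#' @param table a `cohort_table` or a data frame containing `response` and
#'   the predictor columns.
#' @param scope for a `cohort_table`: `"TEA"`, `"GARDEN"` or `"avg"`;
#'   selects which task's parameter columns are offered as predictors.
#' @param response name of the response column (default `fried_score`).
#' @param predictors character vector of predictor column names; defaults
#'   to the nine parameters of `scope`.
#' @param entry p-value threshold to enter (default 0.05).
#' @param removal p-value threshold to remove (default 0.10).
#' @param vif_limit critical variance inflation factor (default 5.0).
#' @return list of class `regression_model`: `response`, `selected`
#'   (ordered), `beta_std` (standardized coefficients), `R2`, `R2_adj`,
#'   `model_p`, `vif`, `n`, and the underlying `fit` (an `lm`, or `NULL`
#'   for the empty model).
#' @export
stepwise_mlr <- function(table, scope = "avg", response = "fried_score",
                         predictors = NULL, entry = 0.05, removal = 0.10,
                         vif_limit = 5.0) {
  if (inherits(table, "cohort_table")) {
    if (is.null(predictors)) {
      predictors <- paste0(kinematic_parameters(), "_", scope)
    }
    df <- as.data.frame(table)[, c(response, predictors)]
  } else {
    if (is.null(predictors)) predictors <- setdiff(names(table), response)
    df <- as.data.frame(table)[, c(response, predictors)]
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  y <- df[[response]]

  selected <- character(0)
  repeat {
    if (n <= length(selected) + 2L) break
    cand <- setdiff(predictors, selected)
    if (!length(cand)) break
    pv <- vapply(cand, function(v) {
      fit <- stats::lm(stats::reformulate(c(selected, v), response), df)
      cf <- summary(fit)$coefficients
      if (!v %in% rownames(cf)) return(1)  # aliased
      cf[v, "Pr(>|t|)"]
    }, numeric(1))
    added <- FALSE
    for (v in cand[order(pv)]) {
      if (pv[v] > entry) break
      vifs <- vif_values(df, c(selected, v))
      if (any(vifs >= vif_limit)) next  # collinear candidate: skip
      selected <- c(selected, v)
      added <- TRUE
      break
    }
    if (!added) break
    # backward pass at the removal threshold
    repeat {
      if (length(selected) < 2L) break
      fit <- stats::lm(stats::reformulate(selected, response), df)
      cf <- summary(fit)$coefficients
      pr <- cf[selected, "Pr(>|t|)"]
      worst <- which.max(pr)
      if (pr[worst] >= removal) {
        selected <- selected[-worst]
      } else break
    }
  }

  if (!length(selected)) {
    return(structure(list(response = response, selected = character(0),
                          beta_std = numeric(0), R2 = 0, R2_adj = 0,
                          model_p = NA_real_, vif = numeric(0), n = n,
                          fit = NULL),
                     class = "regression_model"))
  }
  fit <- stats::lm(stats::reformulate(selected, response), df)
  sm <- summary(fit)
  beta_std <- stats::coef(fit)[selected] *
    vapply(df[selected], stats::sd, numeric(1)) / stats::sd(y)
  fstat <- sm$fstatistic
  model_p <- unname(stats::pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE))
  structure(list(response = response, selected = selected,
                 beta_std = beta_std, R2 = sm$r.squared,
                 R2_adj = sm$adj.r.squared, model_p = model_p,
                 vif = vif_values(df, selected), n = n, fit = fit),
            class = "regression_model")
}

# variance inflation factors: 1 / (1 - R^2 of predictor j on the others)
vif_values <- function(df, predictors) {
  if (length(predictors) < 2L) {
    return(stats::setNames(rep(1, length(predictors)), predictors))
  }
  vapply(stats::setNames(predictors, predictors), function(v) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(predictors, v), v),
                            df))$r.squared
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' @export
print.regression_model <- function(x, ...) {
  if (!length(x$selected)) {
    cat(sprintf("<regression_model> %s: empty model (no predictor met entry), R2 = 0\n",
                x$response))
    return(invisible(x))
  }
  cat(sprintf("<regression_model> %s ~ %s\n", x$response,
              paste(x$selected, collapse = " + ")))
  cat(sprintf("  R2 = %.3f (adj %.3f), model p = %.4f, n = %d\n",
              x$R2, x$R2_adj, x$model_p, x$n))
  for (v in x$selected) {
    cat(sprintf("  %-12s beta_std = %+.3f  VIF = %.2f\n", v,
                x$beta_std[[v]], x$vif[[v]]))
  }
  invisible(x)
}

#' Pooled mean from subgroup means and sizes
#'
#' Size-weighted mean, used to cross-check printed cohort totals against
#' subgroup summaries.
#'
#' @param means subgroup means.
#' @param ns subgroup sizes.
#' @return the pooled mean.
#' @export
#' @examples
#' pooled_mean(c(78.4, 79.8, 89.8), c(8, 13, 6))
pooled_mean <- function(means, ns) {
  stopifnot(length(means) == length(ns), all(ns > 0))
  sum(means * ns) / sum(ns)
}
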