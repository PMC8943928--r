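#' Run the full analysis pipeline
#'
#' Chains every stage into one reproducible run: simulate a cohort (or
#' read one from `input_dir`), preprocess all recordings, extract the
#' nine-parameter profiles, merge the frailty assessments, and run the
#' statistics stage (per-parameter group ANOVAs with Tukey post hoc tests
#' for each task and the task average, inter-task correlations, the
#' permutation multivariate group test, and the stepwise regressions of
#' the frailty score). All outputs are written as CSV plus a
#' machine-readable run log; identical configuration and seed give
#' identical outputs.
#'
#' @param config a [sim_config()]; its seed drives all randomness.
#' @param out_dir output directory (created if needed).
#' @param n_per_group cohort composition for simulation.
#' @param input_dir optional directory with an existing `manifest.csv`
#'   and recordings (as written by [write_cohort()]); when given, no
#'   simulation is performed.
#' @param n_perm permutations for the multivariate test.
#' @param write_recordings also write the simulated raw recordings
#'   (default `FALSE`; the feature table is always written).
#' @param pre_cfg,feat_cfg preprocessing and feature configurations.
#' @param keep_going log and skip recordings that fail a stage instead of
#'   aborting.
#' @return invisibly, a list with `features`, `table` (the wide
#'   `cohort_table`), `comparisons`, `correlations`, `regressions`, and
#'   `multivariate`.
#' @export
run_pipeline <- function(config = default_sim_config(),
                         out_dir,
                         n_per_group = c(R = 8, P = 13, F = 6),
                         input_dir = NULL,
                         n_perm = 2000,
                         write_recordings = FALSE,
                         pre_cfg = preprocess_config(),
                         feat_cfg = feature_config(),
                         keep_going = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(input_dir)) {
    cohort <- simulate_cohort(config, n_per_group)
    if (write_recordings) write_cohort(cohort, file.path(out_dir, "recordings"))
    features <- extract_cohort_features(cohort, pre_cfg, feat_cfg)
  } else {
    manifest <- utils::read.csv(file.path(input_dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
    if (any(duplicated(manifest[, c("participant_id", "task")]))) {
      stop("duplicate participant x task rows in manifest")
    }
    rows <- list()
    for (i in seq_len(nrow(manifest))) {
      res <- tryCatch({
        raw <- read_recording(file.path(input_dir, manifest$file[i]),
                              participant_id = manifest$participant_id[i],
                              task = manifest$task[i])
        prof <- extract_profile(preprocess(raw, pre_cfg), feat_cfg)
        cbind(prof, group = manifest$group[i],
              fried_score = manifest$fried_score[i],
              stringsAsFactors = FALSE)
      }, error = function(e) {
        msg <- sprintf("recording %s/%s failed: %s",
                       manifest$participant_id[i], manifest$task[i],
                       conditionMessage(e))
        if (!keep_going) stop(msg, call. = FALSE)
        warning(msg, call. = FALSE)
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    features <- do.call(rbind, rows)
  }
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  tab <- build_cohort_table(features)
  params <- kinematic_parameters()

  comparisons <- do.call(rbind, lapply(c("avg", "TEA", "GARDEN"), function(sc) {
    do.call(rbind, lapply(params, function(pm) {
      v <- tab[[paste0(pm, "_", sc)]]
      res <- tryCatch(compare_groups(v, tab$group, pm),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(scope = sc, parameter = pm, F = res$F,
                 df1 = res$df[1], df2 = res$df[2], p = res$p,
                 eta2p = res$eta2p,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(comparisons)) {
    comparisons <- data.frame(scope = character(0), parameter = character(0),
                              F = numeric(0), df1 = numeric(0),
                              df2 = numeric(0), p = numeric(0),
                              eta2p = numeric(0))
  }
  utils::write.csv(comparisons, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)

  correlations <- do.call(rbind, lapply(params, function(pm) {
    res <- tryCatch(suppressWarnings(inter_task_correlation(tab, pm)),
                    error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = NA_integer_))
    data.frame(parameter = pm, r = res$r, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)

  regressions <- list()
  for (sc in c("avg", "TEA", "GARDEN")) {
    mod <- stepwise_mlr(tab, scope = sc)
    regressions[[sc]] <- mod
    df <- if (length(mod$selected)) {
      data.frame(scope = sc, predictor = mod$selected,
                 beta_std = unname(mod$beta_std), vif = unname(mod$vif),
                 R2 = mod$R2, R2_adj = mod$R2_adj, model_p = mod$model_p,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(scope = sc, predictor = NA_character_, beta_std = NA_real_,
                 vif = NA_real_, R2 = 0, R2_adj = 0, model_p = NA_real_,
                 stringsAsFactors = FALSE)
    }
    utils::write.csv(df, file.path(out_dir, sprintf("regression_%s.csv", sc)),
                     row.names = FALSE)
  }

  mv <- multivariate_group_test(tab, n_perm = n_perm,
                                seed = derive_seed(config$seed, "perm"))

  log <- list(seed = config$seed,
              n_perm = n_perm,
              sample_rate = config$sample_rate,
              gravity = config$gravity,
              n_participants = nrow(tab),
              config_hash = stable_hash(paste(utils::capture.output(
                utils::str(config)), collapse = "\n")),
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("adlkin")))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  report_tables(tab, comparisons, correlations, regressions, mv,
                file.path(out_dir, "report.txt"))

  invisible(list(features = features, table = tab,
                 comparisons = comparisons, correlations = correlations,
                 regressions = regressions, multivariate = mv))
}

# plain-text report mirroring the cohort-summary layout: cell means (SD),
# ANOVA p / eta2p per scope, correlations, and the regression models
report_tables <- function(tab, comparisons, correlations, regressions, mv,
                          path) {
  params <- kinematic_parameters()
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Kinematic group comparison report")
  w("=================================")
  w("")
  w("Multivariate permutation group test: statistic = %.2f, p = %.4f (n_perm = %d)",
    mv$statistic, mv$p, mv$n_perm)
  w("")
  for (sc in c("avg", "TEA", "GARDEN")) {
    w("Scope: %s", sc)
    w("%-8s %10s %10s %10s %8s %8s", "param", "R", "P", "F", "p", "eta2p")
    for (pm in params) {
      v <- tab[[paste0(pm, "_", sc)]]
      cell <- vapply(c("R", "P", "F"), function(gp) {
        x <- v[tab$group == gp]
        sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                stats::sd(x, na.rm = TRUE))
      }, character(1))
      cmp <- if (is.null(comparisons)) NULL else {
        comparisons[comparisons$scope == sc & comparisons$parameter == pm, ]
      }
      has_cmp <- !is.null(cmp) && nrow(cmp) > 0
      w("%-8s %10s %10s %10s %8.3f %8.3f", pm, cell[1], cell[2], cell[3],
        if (has_cmp) cmp$p else NA_real_,
        if (has_cmp) cmp$eta2p else NA_real_)
    }
    w("")
  }
  w("Inter-task correlations (TEA vs GARDEN)")
  for (i in seq_len(nrow(correlations))) {
    w("  %-8s r = %+.2f, p = %.3f", correlations$parameter[i],
      correlations$r[i], correlations$p[i])
  }
  w("")
  w("Stepwise regressions of the frailty score")
  for (sc in names(regressions)) {
    m <- regressions[[sc]]
    if (!length(m$selected)) {
      w("  %s: empty model", sc)
    } else {
      w("  %s: %s | R2 = %.3f (adj %.3f), p = %.4f", sc,
        paste(sprintf("%s (beta %.2f)", m$selected, m$beta_std),
              collapse = ", "),
        m$R2, m$R2_adj, m$model_p)
    }
  }
}
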