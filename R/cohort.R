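#' Extract kinematic profiles for a whole cohort
#'
#' Preprocesses every recording of a simulated cohort and extracts the
#' nine-parameter profile, returning one long feature table.
#'
#' @param cohort an `adl_cohort` from [simulate_cohort()].
#' @param pre_cfg a [preprocess_config()].
#' @param feat_cfg a [feature_config()].
#' @return data frame with one row per participant x task: identifiers,
#'   `group`, `fried_score`, and the nine parameters.
#' @export
extract_cohort_features <- function(cohort,
                                    pre_cfg = preprocess_config(),
                                    feat_cfg = feature_config()) {
  rows <- lapply(cohort, function(part) {
    do.call(rbind, lapply(names(part$recordings), function(task) {
      prof <- extract_profile(preprocess(part$recordings[[task]], pre_cfg),
                              feat_cfg)
      cbind(prof, group = part$group, fried_score = part$score,
            stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the wide cohort table used by the statistics stage
#'
#' Pivots the long feature table (one row per participant x task) into a
#' wide table with one row per participant: for each kinematic parameter
#' a `<param>_TEA`, `<param>_GARDEN`, and `<param>_avg` column, plus group
#' and frailty score. Participants missing one task are flagged
#' (`complete = FALSE`) and their task-average columns left `NA`.
#'
#' @param features long feature table as produced by
#'   [extract_cohort_features()] (columns `participant_id`, `task`,
#'   `group`, `fried_score`, and the nine parameters).
#' @return data frame of class `cohort_table`.
#' @export
build_cohort_table <- function(features) {
  params <- kinematic_parameters()
  stopifnot(all(c("participant_id", "task", "group", "fried_score", params)
                %in% names(features)))
  if (any(duplicated(features[, c("participant_id", "task")]))) {
    stop("duplicate participant x task rows; each ADL is performed once")
  }
  ids <- unique(features$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- features[features$participant_id == id, ]
    row <- data.frame(participant_id = id, group = sub$group[1],
                      fried_score = sub$fried_score[1],
                      stringsAsFactors = FALSE)
    complete <- all(c("TEA", "GARDEN") %in% sub$task)
    for (pm in params) {
      for (task in c("TEA", "GARDEN")) {
        v <- sub[[pm]][sub$task == task]
        row[[paste0(pm, "_", task)]] <- if (length(v)) v else NA_real_
      }
      row[[paste0(pm, "_avg")]] <- if (complete) {
        mean(c(row[[paste0(pm, "_TEA")]], row[[paste0(pm, "_GARDEN")]]))
      } else NA_real_
    }
    row$complete <- complete
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Per-participant task averages
#'
#' Arithmetic mean of the TEA and GARDEN value of each kinematic
#' parameter per participant. Rows missing one task are excluded.
#'
#' @param table a `cohort_table` from [build_cohort_table()].
#' @return data frame with `participant_id`, `group`, `fried_score`, and
#'   one averaged column per parameter.
#' @export
task_average <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  keep <- table$complete
  cols <- paste0(kinematic_parameters(), "_avg")
  out <- table[keep, c("participant_id", "group", "fried_score", cols)]
  names(out) <- sub("_avg$", "", names(out))
  rownames(out) <- NULL
  out
}
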