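#' Criterion names of the adapted Fried frailty phenotype
#'
#' @return the five criterion names: unintentional weight loss,
#'   exhaustion, low physical activity, low grip strength, slow walking
#'   speed.
#' @export
fried_criteria_names <- function() {
  c("weight_loss", "exhaustion", "low_physical_activity",
    "low_grip_strength", "slow_walking_speed")
}

#' Adapted Fried frailty score
#'
#' Counts positive criteria among the five adapted Fried phenotype
#' criteria. All five must be present and adjudicated (no imputation of
#' missing criteria).
#'
#' @param criteria named logical vector (or coercible 0/1) containing all
#'   of [fried_criteria_names()].
#' @return integer score 0-5.
#' @export
#' @examples
#' fried_score(c(weight_loss = FALSE, exhaustion = TRUE,
#'               low_physical_activity = FALSE, low_grip_strength = TRUE,
#'               slow_walking_speed = FALSE))  # 2
fried_score <- function(criteria) {
  nms <- fried_criteria_names()
  criteria <- unlist(criteria)
  if (!all(nms %in% names(criteria))) {
    stop("missing frailty criteria: ",
         paste(setdiff(nms, names(criteria)), collapse = ", "))
  }
  vals <- as.logical(criteria[nms])
  if (anyNA(vals)) stop("frailty criteria must be adjudicated (no NA)")
  sum(vals)
}

#' Categorize a frailty score
#'
#' Maps the adapted Fried score to the phenotype category: 0 failures =
#' robust (R), 1-2 = pre-frail (P), 3 or more = frail (F).
#'
#' @param score integer (vector) in 0-5.
#' @return factor with levels `R`, `P`, `F`.
#' @export
#' @examples
#' categorize_frailty(0:5)
categorize_frailty <- function(score) {
  score <- as.integer(score)
  if (anyNA(score) || any(score < 0L | score > 5L)) {
    stop("frailty score must be an integer in 0..5")
  }
  factor(ifelse(score == 0L, "R", ifelse(score <= 2L, "P", "F")),
         levels = c("R", "P", "F"))
}

#' Assess frailty from criterion booleans
#'
#' Convenience wrapper combining [fried_score()] and
#' [categorize_frailty()].
#'
#' @param criteria as in [fried_score()].
#' @return list with `score` (0-5) and `category` (factor R/P/F).
#' @export
frailty_assessment <- function(criteria) {
  s <- fried_score(criteria)
  list(score = s, category = categorize_frailty(s))
}
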