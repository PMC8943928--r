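#' Reference cohort summary statistics
#'
#' Group-level descriptive statistics of the frailty cohort the synthetic
#' generator emulates: group sizes and the means (standard deviations) of
#' age, grip strength and Mini Mental State Examination score for the
#' robust (R), pre-frail (P) and frail (F) groups, together with the
#' printed whole-cohort totals.
#'
#' @return list with `groups` (data frame: `group`, `n`, `age_mean`,
#'   `grip_mean`, `mmse_mean`) and `totals` (named vector of the printed
#'   pooled means).
#' @export
#' @examples
#' ref <- reference_cohort_summary()
#' pooled_mean(ref$groups$age_mean, ref$groups$n)
reference_cohort_summary <- function() {
  list(
    groups = data.frame(
      group = c("R", "P", "F"),
      n = c(8L, 13L, 6L),
      age_mean = c(78.4, 79.8, 89.8),
      grip_mean = c(24.4, 19.4, 10.8),
      mmse_mean = c(28.1, 27.5, 25.8),
      stringsAsFactors = FALSE
    ),
    totals = c(age = 81.6, grip = 19.0, mmse = 27.3)
  )
}

#' Reference adapted-Fried score distribution
#'
#' The per-participant frailty scores of the reference cohort: eight
#' participants scored 0, six scored 1, seven scored 2, three scored 3
#' and three scored 4.
#'
#' @return integer vector of 27 scores.
#' @export
#' @examples
#' table(categorize_frailty(reference_score_distribution()))
reference_score_distribution <- function() {
  rep(0:4, times = c(8L, 6L, 7L, 3L, 3L))
}

#' Reference group-by-task kinematic cell means
#'
#' Published group-by-task means (and standard deviations) of the nine
#' kinematic parameters for the reference cohort; the calibration targets
#' of [default_sim_config()] are the TD, RA and MPA cells.
#'
#' @return data frame with one row per group x task and columns
#'   `group`, `task`, `<param>_mean` and `<param>_sd` for the nine
#'   parameters.
#' @export
reference_cell_means <- function() {
  df <- read.csv(text = "
group,task,TD_mean,TD_sd,RA_mean,RA_sd,STD_mean,STD_sd,PPS_mean,PPS_sd,RATIO_mean,RATIO_sd,SUM_mean,SUM_sd,APS_mean,APS_sd,MPA_mean,MPA_sd,MAX95_mean,MAX95_sd
R,TEA,137,28,0.40,0.08,0.60,0.11,3.4,0.2,0.36,0.10,22.81,7.76,16.30,3.06,0.39,0.09,0.99,0.19
P,TEA,150,42,0.44,0.16,0.51,0.11,3.7,0.4,0.32,0.09,24.15,11.90,17.61,8.27,0.38,0.14,0.95,0.27
F,TEA,147,30,0.51,0.12,0.42,0.16,3.9,0.2,0.34,0.05,30.79,9.67,20.57,2.82,0.38,0.05,0.83,0.24
R,GARDEN,96,32,0.74,0.03,0.88,0.18,3.3,0.2,0.75,0.05,24.93,9.24,25.80,4.43,0.94,0.18,1.78,0.39
P,GARDEN,117,76,0.66,0.11,0.71,0.20,3.3,0.4,0.64,0.12,26.24,18.77,22.26,5.14,0.69,0.20,1.42,0.39
F,GARDEN,90,59,0.61,0.15,0.61,0.24,3.6,0.4,0.60,0.15,21.99,17.05,22.92,7.09,0.61,0.25,1.19,0.50
", stringsAsFactors = FALSE)
  df
}

#' Reference whole-cohort task means
#'
#' Published task-level trial-duration means for the reference cohort,
#' used as an arithmetic cross-check against the pooled group-by-task
#' cells.
#'
#' @return named vector: `TEA_TD` and `GARDEN_TD` in seconds.
#' @export
reference_task_means <- function() {
  c(TEA_TD = 145, GARDEN_TD = 105)
}
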