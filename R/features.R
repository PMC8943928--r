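#' Feature-extraction configuration
#'
#' @param activity_threshold magnitude threshold (m/s^2) above which a
#'   sample counts as active (relative activity, RA). Strict ">".
#' @param prominence_threshold minimum peak prominence (m/s^2) for a peak
#'   to count as a distinct movement (peak ratio, RATIO). Inclusive ">=".
#' @param percentile percentile of peak heights used for the
#'   outlier-robust intensity measure MAX95 (default 95).
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(activity_threshold = 0.2,
                           prominence_threshold = 0.2,
                           percentile = 95) {
  stopifnot(activity_threshold > 0, prominence_threshold > 0,
            percentile > 0, percentile < 100)
  structure(list(activity_threshold = activity_threshold,
                 prominence_threshold = prominence_threshold,
                 percentile = percentile),
            class = "feature_config")
}

#' Trial duration (TD)
#'
#' Time to execute the task in seconds: number of samples divided by the
#' sample rate. Start and stop are the recording bounds.
#'
#' @param sig a `magnitude_signal`.
#' @return duration in seconds (0 with a warning for an empty series).
#' @export
trial_duration <- function(sig) {
  n <- length(signal_vector(sig))
  if (n == 0L) {
    warning("empty signal: trial duration 0")
    return(0)
  }
  n / sig$sample_rate
}

#' Relative activity (RA)
#'
#' Fraction of the trial in which the preprocessed acceleration magnitude
#' exceeds the activity threshold (default 0.2 m/s^2); 1.0 indicates the
#' absence of any inactivity.
#'
#' @param sig a `magnitude_signal`.
#' @param cfg a [feature_config()].
#' @return dimensionless fraction in \[0, 1\].
#' @export
relative_activity <- function(sig, cfg = feature_config()) {
  a <- signal_vector(sig)
  stopifnot(length(a) > 0)
  mean(a > cfg$activity_threshold)
}

#' Peak standard deviation (STD)
#'
#' Sample standard deviation (n - 1 denominator) of all acceleration peak
#' heights; the "agility" measure. Low values indicate monotonous
#' movement execution.
#'
#' @param peaks a `peak_set` from [detect_peaks()].
#' @return STD in m/s^2, or `NA` when fewer than 2 peaks exist.
#' @export
peak_std <- function(peaks) {
  if (nrow(peaks) < 2L) return(NA_real_)
  stats::sd(peaks$height)
}

#' Peaks per second (PPS)
#'
#' Number of acceleration peaks per second, a movement-smoothness measure
#' (more peaks per second = less smooth).
#'
#' @param peaks a `peak_set`.
#' @param TD trial duration in seconds (> 0).
#' @return PPS in 1/s.
#' @export
peaks_per_second <- function(peaks, TD) {
  stopifnot(TD > 0)
  nrow(peaks) / TD
}

#' Peak ratio (RATIO)
#'
#' Ratio of acceleration peaks with at least the threshold prominence
#' (default 0.2 m/s^2) to all acceleration peaks: distinct movements
#' relative to all movements including noise.
#'
#' @param peaks a `peak_set`.
#' @param cfg a [feature_config()].
#' @return dimensionless ratio in \[0, 1\], `NA` when no peaks exist.
#' @export
peak_ratio <- function(peaks, cfg = feature_config()) {
  if (nrow(peaks) == 0L) return(NA_real_)
  mean(peaks$prominence >= cfg$prominence_threshold)
}

#' Weighted sum of acceleration per second (SUM)
#'
#' Sum of squared magnitudes divided by trial duration (equivalently the
#' mean squared acceleration times the sample rate), in m^2/s^5. The
#' square down-weights noise and small movements; a nonlinear energy
#' estimate.
#'
#' @param sig a `magnitude_signal`.
#' @return SUM in m^2/s^5.
#' @export
weighted_sum_acc <- function(sig) {
  a <- signal_vector(sig)
  TD <- trial_duration(sig)
  if (TD == 0) return(0)
  sum(a^2) / TD
}

#' Acceleration per second (APS)
#'
#' Sum of magnitudes divided by trial duration (mean magnitude times
#' sample rate), in m/s^3; a linear energy-expenditure measure.
#'
#' @param sig a `magnitude_signal`.
#' @return APS in m/s^3.
#' @export
acc_per_second <- function(sig) {
  a <- signal_vector(sig)
  TD <- trial_duration(sig)
  if (TD == 0) return(0)
  sum(a) / TD
}

#' Mean peak acceleration (MPA)
#'
#' Arithmetic mean of all acceleration peak heights, an intensity measure.
#'
#' @param peaks a `peak_set`.
#' @return MPA in m/s^2, `NA` when no peaks exist.
#' @export
mean_peak_acc <- function(peaks) {
  if (nrow(peaks) == 0L) return(NA_real_)
  mean(peaks$height)
}

#' 95th percentile of acceleration peaks (MAX95)
#'
#' Outlier-robust intensity measure: the 95th percentile of all peak
#' heights, by linear interpolation between order statistics (quantile
#' position (n - 1) p).
#'
#' @param peaks a `peak_set`.
#' @param cfg a [feature_config()].
#' @return MAX95 in m/s^2, `NA` when no peaks exist.
#' @export
max95 <- function(peaks, cfg = feature_config()) {
  if (nrow(peaks) == 0L) return(NA_real_)
  unname(stats::quantile(peaks$height, cfg$percentile / 100, type = 7))
}

#' Extract the nine-parameter kinematic profile
#'
#' Computes all nine kinematic parameters from one preprocessed magnitude
#' signal with a single peak-detection pass:
#'
#' * activity: `TD` (s), `RA` (-)
#' * agility: `STD` (m/s^2)
#' * smoothness: `PPS` (1/s), `RATIO` (-)
#' * energy: `SUM` (m^2/s^5), `APS` (m/s^3)
#' * intensity: `MPA` (m/s^2), `MAX95` (m/s^2)
#'
#' Parameters undefined for the signal at hand (e.g. `STD` with fewer than
#' two peaks) are reported as `NA`, never as zero.
#'
#' @param sig a `magnitude_signal`.
#' @param cfg a [feature_config()].
#' @return a one-row data frame of class `kinematic_profile` with columns
#'   `participant_id`, `task`, and the nine parameters.
#' @export
#' @examples
#' rec <- simulate_recording(default_sim_config(seed = 1), "R", "GARDEN", "P01")
#' extract_profile(preprocess(rec$recording))
extract_profile <- function(sig, cfg = feature_config()) {
  stopifnot(inherits(sig, "magnitude_signal"))
  peaks <- suppressWarnings(detect_peaks(sig))
  TD <- trial_duration(sig)
  out <- data.frame(
    participant_id = sig$participant_id %||% NA_character_,
    task = sig$task %||% NA_character_,
    TD = TD,
    RA = relative_activity(sig, cfg),
    STD = peak_std(peaks),
    PPS = if (TD > 0) peaks_per_second(peaks, TD) else NA_real_,
    RATIO = peak_ratio(peaks, cfg),
    SUM = weighted_sum_acc(sig),
    APS = acc_per_second(sig),
    MPA = mean_peak_acc(peaks),
    MAX95 = max95(peaks, cfg),
    stringsAsFactors = FALSE
  )
  class(out) <- c("kinematic_profile", "data.frame")
  out
}

#' Names of the nine kinematic parameters
#'
#' @return character vector `TD, RA, STD, PPS, RATIO, SUM, APS, MPA, MAX95`.
#' @export
kinematic_parameters <- function() {
  c("TD", "RA", "STD", "PPS", "RATIO", "SUM", "APS", "MPA", "MAX95")
}
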