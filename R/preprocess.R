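#' Preprocessing configuration
#'
#' Bundles the parameters of the raw-to-magnitude preprocessing chain:
#' constant gravity subtraction, rectification, and local-regression
#' smoothing over a short centred window.
#'
#' @param gravity gravitational constant subtracted from the magnitude,
#'   in m/s^2. Fixed, not estimated from a static baseline.
#' @param smooth_window smoothing window length in seconds (default 0.420 s).
#' @param loess_degree polynomial degree of the local regression (default 2).
#' @param rectify logical; take the absolute value after subtracting gravity
#'   (default `TRUE`).
#' @return an object of class `preprocess_config`.
#' @export
#' @examples
#' preprocess_config()
preprocess_config <- function(gravity = 9.81, smooth_window = 0.420,
                              loess_degree = 2L, rectify = TRUE) {
  stopifnot(is.numeric(gravity), gravity >= 0,
            is.numeric(smooth_window), smooth_window > 0,
            loess_degree >= 0, is.logical(rectify))
  structure(list(gravity = gravity, smooth_window = smooth_window,
                 loess_degree = as.integer(loess_degree), rectify = rectify),
            class = "preprocess_config")
}

#' Euclidean acceleration magnitude
#'
#' Per-sample Euclidean norm of the tri-axial acceleration vector.
#'
#' @param raw a `raw_recording` (see [simulate_recording()],
#'   [read_recording()]) or an n x 3 numeric matrix of accelerations in
#'   m/s^2.
#' @return numeric vector of per-sample magnitudes, same length as the
#'   input series.
#' @export
#' @examples
#' acc_magnitude(matrix(c(3, 4, 0), nrow = 1))  # 5
acc_magnitude <- function(raw) {
  axyz <- if (inherits(raw, "raw_recording")) raw$axyz else raw
  axyz <- as.matrix(axyz)
  if (ncol(axyz) != 3L) stop("expected a tri-axial (n x 3) series")
  bad <- which(!is.finite(axyz), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite acceleration sample at index %d (axis %d)",
                 bad[1, 1], bad[1, 2]))
  }
  sqrt(rowSums(axyz^2))
}

#' Remove the gravity component from a magnitude series
#'
#' Subtracts a constant gravitational acceleration from the magnitude
#' series and optionally rectifies (absolute value) the result, so that a
#' resting sensor maps to zero.
#'
#' @param mag numeric vector of acceleration magnitudes (m/s^2).
#' @param cfg a [preprocess_config()].
#' @return numeric vector, `abs(mag - gravity)` when `cfg$rectify`, else
#'   `mag - gravity`.
#' @export
#' @examples
#' remove_gravity(c(9.81, 10.01, 9.00))  # 0, 0.2, 0.81
remove_gravity <- function(mag, cfg = preprocess_config()) {
  out <- mag - cfg$gravity
  if (cfg$rectify) out <- abs(out)
  out
}

# Tricube weights for integer offsets d within half-width m; the bandwidth
# is m + 1 so every sample in the window keeps positive weight.
tricube_weights <- function(d, m) {
  (1 - (abs(d) / (m + 1))^3)^3
}

#' Local-regression (loess-type) smoothing with a fixed time window
#'
#' Locally weighted polynomial regression with tricube weights over a
#' centred window of fixed duration, the smoother applied to the rectified
#' acceleration magnitude before feature extraction. The span is the
#' window duration times the sample rate, rounded up to an odd sample
#' count so windows are centred; windows are truncated (not reflected) at
#' the series edges.
#'
#' Interior samples share one design matrix, so their fitted values reduce
#' to a single convolution kernel; only the edge samples need individual
#' weighted least-squares fits.
#'
#' @param sig numeric vector to smooth.
#' @param sample_rate sampling frequency in Hz.
#' @param window window length in seconds (default 0.420).
#' @param degree local polynomial degree (default 2).
#' @return numeric vector of smoothed values, same length as `sig`.
#' @export
#' @examples
#' smooth_loess(sin(seq(0, 2 * pi, length.out = 200)), sample_rate = 100)
smooth_loess <- function(sig, sample_rate, window = 0.420, degree = 2L) {
  n <- length(sig)
  degree <- as.integer(degree)
  k0 <- round(window * sample_rate)
  k <- as.integer(2L * floor(k0 / 2) + 1L)  # odd span
  if (k < degree + 2L) {
    stop(sprintf("smoothing window spans %d samples; need at least %d for degree %d",
                 k, degree + 2L, degree))
  }
  if (n == 0L) return(numeric(0))
  m <- (k - 1L) %/% 2L

  fit_at <- function(i) {
    lo <- max(1L, i - m)
    hi <- min(n, i + m)
    d <- (lo:hi) - i
    w <- tricube_weights(d, m)
    X <- outer(d, 0:degree, `^`)
    fit <- stats::lm.wfit(X, sig[lo:hi], w)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    cf[1]
  }

  if (n <= 2L * m) {
    return(vapply(seq_len(n), fit_at, numeric(1)))
  }

  # interior kernel: fitted value at window centre is linear in the data
  d <- (-m):m
  w <- tricube_weights(d, m)
  X <- outer(d, 0:degree, `^`)
  M <- solve(crossprod(X, w * X))
  kern <- as.numeric((M %*% t(X))[1, ]) * w

  out <- as.numeric(stats::filter(sig, kern, method = "convolution", sides = 2))
  edge <- c(seq_len(m), (n - m + 1L):n)
  out[edge] <- vapply(edge, fit_at, numeric(1))
  out
}

#' Preprocess a raw recording into a magnitude signal
#'
#' Runs the full preprocessing chain: Euclidean magnitude, constant
#' gravity subtraction with rectification, local-regression smoothing, and
#' clipping of any residual negatives introduced by the smoother. Feature
#' extraction operates on the result.
#'
#' Recordings with irregular timestamps (more than 1% of intervals
#' deviating by more than 10% from the nominal sample period) are resampled
#' onto the regular grid by linear interpolation, with a warning.
#'
#' @param raw a `raw_recording` object.
#' @param cfg a [preprocess_config()].
#' @return an object of class `magnitude_signal` with elements `a`
#'   (non-negative magnitude series, m/s^2), `sample_rate`, `duration`
#'   (seconds), `participant_id`, `task`, and `provenance` (the applied
#'   configuration).
#' @export
#' @examples
#' rec <- simulate_recording(default_sim_config(seed = 1), "R", "TEA", "P01")
#' sig <- preprocess(rec$recording)
#' sig
preprocess <- function(raw, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "raw_recording"))
  t <- raw$t
  axyz <- raw$axyz
  if (length(t) > 1L) {
    dt <- diff(t)
    nominal <- 1 / raw$sample_rate
    frac_bad <- mean(abs(dt - nominal) > 0.10 * nominal)
    if (frac_bad > 0.01) {
      warning(sprintf("%.1f%% of sample intervals deviate >10%% from nominal; resampling to %g Hz",
                      100 * frac_bad, raw$sample_rate))
      grid <- seq(t[1], t[length(t)], by = nominal)
      axyz <- vapply(1:3, function(j) {
        stats::approx(t, axyz[, j], xout = grid)$y
      }, numeric(length(grid)))
      t <- grid
    }
  }
  mag <- acc_magnitude(axyz)
  a <- remove_gravity(mag, cfg)
  a <- smooth_loess(a, raw$sample_rate, cfg$smooth_window, cfg$loess_degree)
  a <- pmax(a, 0)
  structure(list(a = a,
                 sample_rate = raw$sample_rate,
                 duration = length(a) / raw$sample_rate,
                 participant_id = raw$participant_id,
                 task = raw$task,
                 provenance = cfg),
            class = "magnitude_signal")
}

#' @export
print.magnitude_signal <- function(x, ...) {
  cat(sprintf("<magnitude_signal> %s / %s: %d samples @ %g Hz (%.1f s), peak %.2f m/s^2\n",
              x$participant_id %||% "?", x$task %||% "?", length(x$a),
              x$sample_rate, x$duration,
              if (length(x$a)) max(x$a) else NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording from CSV
#'
#' Reads the `t,ax,ay,az` CSV dialect written by [write_cohort()]:
#' seconds and m/s^2, decimal point, one header row.
#'
#' @param path path to the CSV file.
#' @param participant_id,task metadata attached to the recording; defaults
#'   parsed from the file name are not attempted.
#' @param sample_rate sampling rate in Hz; if `NULL`, the median timestamp
#'   interval is used.
#' @return a `raw_recording` object.
#' @export
read_recording <- function(path, participant_id = NA_character_,
                           task = NA_character_, sample_rate = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "ax", "ay", "az") %in% names(df)))
  if (is.null(sample_rate)) {
    sample_rate <- 1 / stats::median(diff(df$t))
  }
  new_raw_recording(participant_id, task, sample_rate, df$t,
                    cbind(df$ax, df$ay, df$az))
}

new_raw_recording <- function(participant_id, task, sample_rate, t, axyz) {
  stopifnot(length(t) == nrow(axyz), sample_rate > 0)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  structure(list(participant_id = participant_id, task = task,
                 sample_rate = sample_rate, t = t, axyz = axyz),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s / %s: %d samples @ %g Hz\n",
              x$participant_id %||% "?", x$task %||% "?", length(x$t),
              x$sample_rate))
  invisible(x)
}
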