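# Independent brute-force oracles. These deliberately re-derive every
# quantity with explicit loops / elementary arithmetic, sharing no code
# with the implementation they check.

# all strict local maxima (plateaus once, at the first sample), by a
# direct scan over samples
brute_peaks <- function(x) {
  n <- length(x)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      # walk along a (possibly length-1) plateau
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

# topographic prominence by outward walking with explicit loops
brute_prominence <- function(x, i) {
  h <- x[i]
  j <- i - 1L
  lmin <- h
  while (j >= 1L && x[j] <= h) {
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1L
  }
  k <- i + 1L
  rmin <- h
  while (k <= length(x) && x[k] <= h) {
    if (x[k] < rmin) rmin <- x[k]
    k <- k + 1L
  }
  h - max(lmin, rmin)
}

brute_peak_table <- function(x) {
  idx <- brute_peaks(x)
  list(index = idx, height = x[idx],
       prominence = vapply(idx, function(i) brute_prominence(x, i),
                           numeric(1)))
}

# per-window weighted least squares fit via lm(), one window per sample;
# same conventions as the implementation (odd span, tricube over
# half-width + 1, truncation at edges) but a completely separate path
wls_loess_oracle <- function(sig, sample_rate, window = 0.420, degree = 2L) {
  n <- length(sig)
  k <- as.integer(2L * floor(round(window * sample_rate) / 2) + 1L)
  m <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - m)
    hi <- min(n, i + m)
    d <- (lo:hi) - i
    w <- (1 - (abs(d) / (m + 1))^3)^3
    df <- data.frame(y = sig[lo:hi], d = d)
    fit <- stats::lm(y ~ poly(d, degree, raw = TRUE), data = df, weights = w)
    out[i] <- unname(stats::predict(fit, newdata = data.frame(d = 0)))
  }
  out
}

# wrap a bare numeric vector as a magnitude_signal
make_sig <- function(a, sample_rate = 100, participant_id = "T01",
                     task = "TEA") {
  structure(list(a = a, sample_rate = sample_rate,
                 duration = length(a) / sample_rate,
                 participant_id = participant_id, task = task,
                 provenance = preprocess_config()),
            class = "magnitude_signal")
}

# build a peak_set directly from heights/prominences (for threshold ops)
make_peaks <- function(height, prominence = height) {
  structure(data.frame(index = seq_along(height) * 2L, height = height,
                       prominence = prominence),
            class = c("peak_set", "data.frame"))
}

# a minimal single-cell config whose six cells share one parameter set
uniform_config <- function(p, seed = 1L, sample_rate = 100) {
  cells <- as.vector(outer(c("R", "P", "F"), c("TEA", "GARDEN"),
                           paste, sep = "."))
  params <- stats::setNames(rep(list(p), length(cells)), cells)
  sim_config(params, sample_rate = sample_rate, seed = seed)
}

# bursts-only parameter set: no plateau, tremor, sensor noise, or wobble,
# so the magnitude is exactly gravity + burst envelopes
bursts_only_params <- function(burst_rate = 0.5, amp = c(1, 0.3),
                               dur = c(1.5, 0.2), pause_fraction = 0.3,
                               trial_duration = c(60, 0)) {
  group_task_params(burst_rate = burst_rate, burst_duration = dur,
                    burst_peak_amp = amp, pause_fraction = pause_fraction,
                    trial_duration = trial_duration, fixed_pause = NULL,
                    plateau_level = 0, tremor_sd = 0, noise_sd = 0,
                    orientation_wobble = 0)
}

# reconstruct the noiseless burst envelope from ground truth
truth_envelope <- function(truth, n, sample_rate) {
  tt <- (seq_len(n) - 1L) / sample_rate
  env <- numeric(n)
  for (b in seq_along(truth$burst_onsets)) {
    s <- truth$burst_durations[b] / 4
    env <- env + truth$burst_peak_amps[b] *
      exp(-((tt - truth$burst_onsets[b])^2) / (2 * s^2))
  }
  env
}
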