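#' Detect acceleration peaks and their prominences
#'
#' Finds every strict local maximum of the signal (a sample greater than
#' both neighbours); a maximal plateau counts once, at its first sample.
#' Peaks are strictly interior to the series. No minimum height is
#' imposed: the peak universe deliberately includes small noise peaks,
#' since the peak-ratio smoothness measure relates prominent peaks to all
#' movements including noise.
#'
#' Prominence follows the standard topographic definition: the peak height
#' minus the higher of the two lowest points separating the peak from
#' higher terrain on either side (or from the series edge when no higher
#' terrain exists).
#'
#' @param sig a `magnitude_signal` or numeric vector.
#' @return an object of class `peak_set`: a data frame with columns
#'   `index`, `height` and `prominence`. A series shorter than 3 samples
#'   yields an empty `peak_set` with a warning.
#' @export
#' @examples
#' detect_peaks(c(0, 1, 0, 2, 0))
detect_peaks <- function(sig) {
  x <- unname(signal_vector(sig))
  n <- length(x)
  if (n < 3L) {
    warning("series shorter than 3 samples: no peaks")
    return(new_peak_set(integer(0), numeric(0), numeric(0)))
  }
  r <- rle(x)
  nr <- length(r$values)
  if (nr < 3L) return(new_peak_set(integer(0), numeric(0), numeric(0)))
  starts <- cumsum(c(1L, r$lengths[-nr]))
  j <- 2:(nr - 1L)
  is_peak <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  idx <- starts[j][is_peak]
  if (length(idx) == 0L) return(new_peak_set(integer(0), numeric(0), numeric(0)))
  h <- x[idx]
  prom <- vapply(seq_along(idx), function(p) {
    peak_prominence(x, idx[p], h[p])
  }, numeric(1))
  new_peak_set(idx, h, prom)
}

# lean data.frame construction (detect_peaks runs in tight loops)
new_peak_set <- function(index, height, prominence) {
  structure(list(index = index, height = height, prominence = prominence),
            row.names = if (length(index)) {
              c(NA_integer_, -length(index))
            } else integer(0),
            class = c("peak_set", "data.frame"))
}

# Topographic prominence of the peak at index i with height h. Scans
# outward until a strictly higher sample or the series edge; the base on
# each side is the minimum over the scanned stretch.
peak_prominence <- function(x, i, h) {
  n <- length(x)
  left <- x[seq_len(i - 1L)]
  hi <- which(left > h)
  lmin <- if (length(hi)) {
    min(left[(max(hi) + 1L):(i - 1L)])
  } else {
    min(left)
  }
  right <- x[(i + 1L):n]
  hi <- which(right > h)
  rmin <- if (length(hi)) {
    min(right[seq_len(min(hi) - 1L)])
  } else {
    min(right)
  }
  h - max(lmin, rmin)
}

signal_vector <- function(sig) {
  if (inherits(sig, "magnitude_signal")) sig$a else as.numeric(sig)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10), ...)
  invisible(x)
}
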