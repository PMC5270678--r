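#' Remove slow baseline drift from a dF/F trace
#'
#' Spontaneous recordings carry slow (< 0.05 Hz) fluorescence changes from
#' photobleaching, focus drift and hemodynamics. The baseline is estimated
#' with a centered running quantile (default: running median) over a window
#' of `1/(3 * cutoff)` seconds and subtracted; the residual mean is removed
#' so the corrected trace is zero-mean. The running median tracks components
#' below the cutoff while ignoring sparse positive transients entirely, so
#' transient peaks are preserved, and it is idempotent up to tolerance.
#'
#' @param trace numeric vector of dF/F samples.
#' @param frame_rate Hz.
#' @param cutoff drift scale in Hz; components below it are removed.
#'   Must be below the Nyquist frequency.
#' @param window_s baseline window in seconds; default `1/(3 * cutoff)`.
#' @param q quantile used for the baseline (0.5 = median). Lower values
#'   (e.g. 0.2) are appropriate for very dense activity at the cost of a
#'   noise-dependent offset.
#' @return numeric vector, same length, zero mean.
#' @examples
#' x <- 0.3 + 0.2 * sin(2 * pi * 0.01 * (0:1499) / 7)
#' max(abs(correct_baseline(x, 7))) < 0.02
#' @export
correct_baseline <- function(trace, frame_rate, cutoff = 0.05,
                             window_s = NULL, q = 0.5) {
  x <- as.numeric(trace)
  if (!all(is.finite(x))) stop("trace contains non-finite values")
  if (length(x) < 2) stop("trace too short")
  if (cutoff <= 0 || cutoff >= frame_rate / 2) {
    stop("'cutoff' must lie in (0, frame_rate/2)")
  }
  if (length(x) < frame_rate / cutoff) {
    warning("trace shorter than one cutoff period; mean subtraction only")
    return(x - mean(x))
  }
  if (is.null(window_s)) window_s <- 1 / (3 * cutoff)
  k <- round(window_s * frame_rate)
  k <- min(k + (k + 1) %% 2, length(x) - (length(x) + 1) %% 2) # odd, <= n
  if (k < 3) k <- 3
  baseline <- if (q == 0.5) {
    stats::runmed(x, k, endrule = "median")
  } else {
    running_quantile(x, k, q)
  }
  out <- x - as.numeric(baseline)
  out - mean(out)
}

# Centered running quantile with edge windows clipped to the trace.
running_quantile <- function(x, k, q) {
  n <- length(x)
  h <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    stats::quantile(x[max(1, i - h):min(n, i + h)], q, names = FALSE)
  }, numeric(1))
}

#' Detect calcium transients in a baseline-corrected trace
#'
#' A transient is a maximal run of frames on which the trace exceeds
#' `k_sigma` times the noise SD and that lasts at least `min_duration`.
#' The noise SD is estimated robustly as the scaled median absolute
#' deviation, so transients do not contaminate the estimate. Duration runs
#' from the threshold up-crossing to the down-crossing; the amplitude is the
#' maximum within the run; an event is single-peaked when it contains
#' exactly one local maximum above threshold.
#'
#' @param trace baseline-corrected dF/F vector.
#' @param frame_rate Hz.
#' @param k_sigma detection threshold in noise SD units.
#' @param min_duration minimal event duration in seconds; the default keeps
#'   events of at least 2 frames.
#' @param cell_id optional identifier stored in the `cell` column.
#' @return data.frame with columns `cell`, `onset_frame`, `peak_frame`,
#'   `end_frame` (1-based), `onset_s`, `peak_s`, `amplitude`, `duration_s`,
#'   `single_peaked`. Zero rows when the trace is constant (noise SD 0 is
#'   treated as "no events").
#' @export
detect_transients <- function(trace, frame_rate, k_sigma = 3,
                              min_duration = 2 / frame_rate, cell_id = 1L) {
  x <- as.numeric(trace)
  empty <- data.frame(
    cell = integer(0), onset_frame = integer(0), peak_frame = integer(0),
    end_frame = integer(0), onset_s = numeric(0), peak_s = numeric(0),
    amplitude = numeric(0), duration_s = numeric(0), single_peaked = logical(0)
  )
  sigma <- stats::mad(x)
  if (!is.finite(sigma) || sigma == 0) return(empty)
  thr <- k_sigma * sigma
  above <- x > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, ceiling(min_duration * frame_rate))
  if (!any(keep)) return(empty)
  starts <- starts[keep]
  ends <- ends[keep]
  rows <- lapply(seq_along(starts), function(i) {
    seg <- x[starts[i]:ends[i]]
    peak_rel <- which.max(seg)
    n_peaks <- if (length(seg) <= 2) 1L else {
      max(1L, sum(diff(sign(diff(seg))) == -2))
    }
    data.frame(
      cell = cell_id,
      onset_frame = starts[i],
      peak_frame = starts[i] + peak_rel - 1L,
      end_frame = ends[i],
      onset_s = (starts[i] - 1) / frame_rate,
      peak_s = (starts[i] + peak_rel - 2) / frame_rate,
      amplitude = seg[peak_rel],
      duration_s = length(seg) / frame_rate,
      single_peaked = n_peaks == 1L
    )
  })
  do.call(rbind, rows)
}

#' Transient rate and duration summary
#'
#' @param transients transient table from [detect_transients()].
#' @param recording_duration_min recording length in minutes (> 0).
#' @return list with `rate` (transients/min), `durations_s`, `n`.
#' @export
transient_statistics <- function(transients, recording_duration_min) {
  if (recording_duration_min <= 0) stop("recording duration must be positive")
  n <- if (is.null(transients)) 0L else nrow(transients)
  list(
    rate = n / recording_duration_min,
    durations_s = if (n) transients$duration_s else numeric(0),
    n = n
  )
}

#' Detect transients on every cell of a trace matrix
#'
#' @param traces frames x cells matrix of baseline-corrected dF/F.
#' @param frame_rate Hz.
#' @inheritParams detect_transients
#' @return row-bound transient table, `cell` holding the column index.
#' @export
detect_transients_population <- function(traces, frame_rate, k_sigma = 3,
                                         min_duration = 2 / frame_rate) {
  stopifnot(is.matrix(traces))
  tabs <- lapply(seq_len(ncol(traces)), function(j) {
    detect_transients(traces[, j], frame_rate, k_sigma, min_duration, cell_id = j)
  })
  do.call(rbind, tabs)
}
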