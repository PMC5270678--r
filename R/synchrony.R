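#' Per-bin coactive fraction of a population
#'
#' For each time bin (default one frame, ~0.144 s at 7 Hz) the fraction of
#' cells with at least one spike in the bin.
#'
#' @param spike_counts frames x cells matrix of per-frame spike counts.
#' @param frame_rate Hz.
#' @param bin_width bin width in seconds (>= one frame interval).
#' @return list of class `coactivity`: `fraction` (per bin), `bin_s`
#'   (realized bin width in seconds), `times_s` (bin start times).
#' @export
coactivity_histogram <- function(spike_counts, frame_rate,
                                 bin_width = 1 / frame_rate) {
  stopifnot(is.matrix(spike_counts))
  if (ncol(spike_counts) < 1) stop("empty population")
  bin_frames <- round(bin_width * frame_rate)
  if (bin_frames < 1) stop("bin width below one frame interval")
  n <- nrow(spike_counts)
  idx <- (seq_len(n) - 1L) %/% bin_frames + 1L
  active <- (spike_counts > 0) + 0L
  per_bin <- rowsum(active, idx) > 0
  frac <- rowMeans(per_bin)
  structure(
    list(
      fraction = as.numeric(frac),
      bin_s = bin_frames / frame_rate,
      times_s = (unique(idx) - 1L) * bin_frames / frame_rate
    ),
    class = "coactivity"
  )
}

#' Surrogate null distribution for coactivity
#'
#' Each surrogate independently circularly shifts every cell's spike train
#' by a uniform random offset, preserving each cell's rate and
#' autostructure (including its state modulation) while destroying
#' cross-cell alignment. The pooled per-bin coactive fractions of all
#' surrogates form the null; its `1 - alpha` quantile is the significance
#' threshold for synchrony.
#'
#' @inheritParams coactivity_histogram
#' @param n_surrogates number of surrogate populations (>= 100).
#' @param alpha significance level.
#' @param seed optional seed for the surrogate draws.
#' @return list:
#'   \describe{
#'     \item{sig_threshold}{pooled `1 - alpha` quantile of the per-bin null
#'       fractions; exceeding it is significant at per-bin level `alpha`.}
#'     \item{peak_threshold}{`1 - alpha` quantile of each surrogate's
#'       maximal coactive fraction (max statistic); exceeding it is
#'       significant at recording-wise level `alpha` and is the default
#'       criterion for synchrony peaks, which are recording-level
#'       discoveries. A per-bin threshold flags the binomial tail of every
#'       co-aligned high-activity epoch, swamping genuine population events.}
#'     \item{alpha, n_surrogates, pooled}{inputs and the pooled null
#'       fractions.}
#'   }
#' @export
surrogate_null <- function(spike_counts, frame_rate,
                           bin_width = 1 / frame_rate,
                           n_surrogates = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(is.matrix(spike_counts))
  if (n_surrogates < 100) stop("need n_surrogates >= 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(spike_counts)
  nc <- ncol(spike_counts)
  shifted <- spike_counts
  pooled <- vector("list", n_surrogates)
  maxima <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    offs <- sample.int(n, nc, replace = TRUE)
    for (j in seq_len(nc)) {
      o <- offs[j] %% n
      if (o > 0) {
        shifted[, j] <- spike_counts[c((n - o + 1):n, 1:(n - o)), j]
      } else {
        shifted[, j] <- spike_counts[, j]
      }
    }
    frac <- coactivity_histogram(shifted, frame_rate, bin_width)$fraction
    pooled[[s]] <- frac
    maxima[s] <- max(frac)
  }
  pooled <- unlist(pooled)
  list(
    sig_threshold = stats::quantile(pooled, 1 - alpha, names = FALSE),
    peak_threshold = stats::quantile(maxima, 1 - alpha, names = FALSE),
    alpha = alpha,
    n_surrogates = n_surrogates,
    pooled = pooled
  )
}

#' Detect significant synchrony peaks
#'
#' Bins whose coactive fraction exceeds the surrogate threshold are grouped
#' into peaks: supra-threshold bins no more than `merge_gap` bins apart
#' belong to one peak, whose time is that of its maximal bin. A population
#' is flagged as exhibiting synchronous activity when it has at least one
#' peak.
#'
#' @param coactivity a [coactivity_histogram()] result.
#' @param sig_threshold significance threshold on the coactive fraction,
#'   typically `surrogate_null(...)$sig_threshold`.
#' @param merge_gap maximal bin spacing merged into one peak.
#' @return object of class `synchrony_result`: `peaks` (data.frame
#'   `time_s`, `coactive_fraction`), `peaks_per_min`,
#'   `mean_peak_coactivity_pct`, `synchronous`, `sig_threshold`, `bin_s`,
#'   `coactive_fraction`.
#' @export
detect_synchrony_peaks <- function(coactivity, sig_threshold, merge_gap = 1) {
  stopifnot(inherits(coactivity, "coactivity"))
  frac <- coactivity$fraction
  supra <- which(frac > sig_threshold)
  duration_min <- length(frac) * coactivity$bin_s / 60
  if (length(supra) == 0) {
    peaks <- data.frame(time_s = numeric(0), coactive_fraction = numeric(0))
  } else {
    grp <- cumsum(c(1, diff(supra) > merge_gap))
    peaks <- do.call(rbind, lapply(split(supra, grp), function(b) {
      top <- b[which.max(frac[b])]
      data.frame(
        time_s = coactivity$times_s[top],
        coactive_fraction = frac[top]
      )
    }))
    rownames(peaks) <- NULL
  }
  structure(
    list(
      peaks = peaks,
      peaks_per_min = nrow(peaks) / duration_min,
      mean_peak_coactivity_pct = if (nrow(peaks)) {
        100 * mean(peaks$coactive_fraction)
      } else {
        NA_real_
      },
      synchronous = nrow(peaks) > 0,
      sig_threshold = sig_threshold,
      bin_s = coactivity$bin_s,
      coactive_fraction = frac
    ),
    class = "synchrony_result"
  )
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf(
    "synchrony: %d peaks (%.2f /min), mean peak coactivity %.1f%%, threshold %.3f\n",
    nrow(x$peaks), x$peaks_per_min,
    x$mean_peak_coactivity_pct, x$sig_threshold
  ))
  invisible(x)
}

#' One-call synchrony analysis
#'
#' Computes the coactivity histogram, the circular-shift surrogate null and
#' the significant synchrony peaks.
#'
#' @inheritParams surrogate_null
#' @inheritParams detect_synchrony_peaks
#' @param threshold_type `"max"` (default) detects peaks against the
#'   recording-wise max-statistic threshold; `"per_bin"` against the pooled
#'   per-bin quantile (see [surrogate_null()]).
#' @return a `synchrony_result` (see [detect_synchrony_peaks()]).
#' @export
analyze_synchrony <- function(spike_counts, frame_rate,
                              bin_width = 1 / frame_rate,
                              n_surrogates = 1000, alpha = 0.05,
                              merge_gap = 1, seed = NULL,
                              threshold_type = c("max", "per_bin")) {
  threshold_type <- match.arg(threshold_type)
  co <- coactivity_histogram(spike_counts, frame_rate, bin_width)
  nullq <- surrogate_null(
    spike_counts, frame_rate, bin_width,
    n_surrogates = n_surrogates, alpha = alpha, seed = seed
  )
  thr <- if (threshold_type == "max") nullq$peak_threshold else nullq$sig_threshold
  detect_synchrony_peaks(co, thr, merge_gap)
}
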