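# Gaussian smoothing with reflected boundaries; sigma in frames.
gaussian_smooth <- function(x, sigma_frames) {
  if (sigma_frames <= 0) return(x)
  h <- max(1L, ceiling(4 * sigma_frames))
  kern <- stats::dnorm(seq(-h, h), sd = sigma_frames)
  kern <- kern / sum(kern)
  n <- length(x)
  h <- min(h, n - 1L)
  kern <- kern[(length(kern) %/% 2 + 1 - h):(length(kern) %/% 2 + 1 + h)]
  kern <- kern / sum(kern)
  padded <- c(rev(x[seq_len(h)]), x, rev(x[(n - h + 1):n]))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}

#' Smoothed mean population activity
#'
#' Per-frame mean spike count across cells, smoothed with a Gaussian of SD
#' `sigma` seconds (reflected boundaries). Smoothing conserves total mass to
#' within 1%.
#'
#' @param spike_counts frames x cells matrix of per-frame spike counts
#'   (>= 2 cells).
#' @param frame_rate Hz.
#' @param sigma Gaussian SD in seconds. The default (0.5 s, FWHM ~1.2 s)
#'   stays below the shortest reported mean state duration (~2.3 s); a
#'   wider kernel blurs short high states into the low-activity background
#'   and hides the bimodality of the activity density.
#' @return list of class `population_activity`: `values` (spikes/frame,
#'   smoothed), `frame_rate`, `sigma`.
#' @export
population_activity <- function(spike_counts, frame_rate, sigma = 0.5) {
  stopifnot(is.matrix(spike_counts))
  if (ncol(spike_counts) < 2) stop("need >= 2 cells for population activity")
  if (any(!is.finite(spike_counts))) stop("spike counts must be finite")
  raw <- rowMeans(spike_counts)
  sm <- gaussian_smooth(raw, sigma * frame_rate)
  sm[sm < 0] <- 0
  structure(
    list(values = sm, frame_rate = frame_rate, sigma = sigma),
    class = "population_activity"
  )
}

#' Threshold between high and low population states
#'
#' Builds the probability density of the population activity values
#' (Gaussian kernel density, Scott's-rule bandwidth by default), locates its
#' two largest modes and calls the population bimodal when the valley
#' between them dips at least `valley_depth` below the lower mode. The
#' state threshold is the activity value at the valley minimum (midpoint of
#' the minimal plateau when the valley is flat).
#'
#' @param activity a [population_activity()] or numeric vector of activity
#'   values (spikes/frame).
#' @param bw density bandwidth; default Scott's rule.
#' @param valley_depth required relative dip below the lower mode (0.2 =
#'   20%).
#' @return list: `bimodal` (logical), `threshold` (activity value, `NA` if
#'   unimodal), `density` (the smoothed pdf as a data.frame).
#' @export
compute_state_threshold <- function(activity, bw = NULL, valley_depth = 0.2) {
  x <- if (inherits(activity, "population_activity")) activity$values else as.numeric(activity)
  if (length(x) < 10 || stats::sd(x) == 0) {
    return(list(bimodal = FALSE, threshold = NA_real_, density = NULL))
  }
  if (is.null(bw)) bw <- stats::bw.nrd(x)
  d <- stats::density(x, bw = bw, n = 512)
  y <- d$y
  n <- length(y)
  is_max <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  dens <- data.frame(x = d$x, y = y)
  if (length(is_max) < 2) {
    return(list(bimodal = FALSE, threshold = NA_real_, density = dens))
  }
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- y[lo:hi]
  vmin <- min(valley)
  lower_mode <- min(y[lo], y[hi])
  if (vmin > (1 - valley_depth) * lower_mode) {
    return(list(bimodal = FALSE, threshold = NA_real_, density = dens))
  }
  flat <- which(valley <= vmin + 1e-9 * max(y)) + lo - 1L
  thr <- d$x[flat[ceiling(length(flat) / 2)]]
  list(bimodal = TRUE, threshold = thr, density = dens)
}

#' Segment population activity into high/low states
#'
#' Frames above the threshold are labelled high, below low; runs shorter
#' than `min_state_duration` are merged into their neighbours (shortest
#' first). States tile the recording without overlap.
#'
#' @param activity a [population_activity()].
#' @param threshold activity threshold (spikes/frame), typically from
#'   [compute_state_threshold()].
#' @param min_state_duration minimal state duration in seconds; default 2
#'   frames.
#' @return object of class `state_segmentation`: `threshold`, `states`
#'   (data.frame: `label`, `start_s`, `duration_s`, `mean_rate_spm` in
#'   spikes/min per cell), `frame_labels`, `frame_rate`, and per-label mean
#'   durations/rates (`mean_high_s`, `mean_low_s`, `high_rate_spm`,
#'   `low_rate_spm`).
#' @export
segment_states <- function(activity, threshold,
                           min_state_duration = NULL) {
  stopifnot(inherits(activity, "population_activity"))
  fs <- activity$frame_rate
  x <- activity$values
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (is.null(min_state_duration)) min_state_duration <- 2 / fs
  lab <- ifelse(x > threshold, "high", "low")
  min_frames <- max(1L, round(min_state_duration * fs))

  # merge sub-minimal runs into neighbours, shortest first
  repeat {
    r <- rle(lab)
    if (length(r$lengths) == 1 || all(r$lengths >= min_frames)) break
    i <- which.min(r$lengths)
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    lab <- inverse.rle(r)
  }

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mean_rate <- vapply(
    seq_along(starts),
    function(i) mean(x[starts[i]:ends[i]]) * fs * 60,
    numeric(1)
  )
  states <- data.frame(
    label = r$values,
    start_s = (starts - 1) / fs,
    duration_s = r$lengths / fs,
    mean_rate_spm = mean_rate
  )
  hi <- states$label == "high"
  structure(
    list(
      threshold = threshold,
      states = states,
      frame_labels = lab,
      frame_rate = fs,
      bimodal = TRUE,
      mean_high_s = if (any(hi)) mean(states$duration_s[hi]) else NA_real_,
      mean_low_s = if (any(!hi)) mean(states$duration_s[!hi]) else NA_real_,
      high_rate_spm = if (any(hi)) mean(states$mean_rate_spm[hi]) else NA_real_,
      low_rate_spm = if (any(!hi)) mean(states$mean_rate_spm[!hi]) else NA_real_
    ),
    class = "state_segmentation"
  )
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf(
    "state segmentation: %d states | mean high %.2f s @ %.2f spikes/min | mean low %.2f s @ %.2f spikes/min\n",
    nrow(x$states), x$mean_high_s, x$high_rate_spm, x$mean_low_s, x$low_rate_spm
  ))
  invisible(x)
}

#' Does a cell fire in accordance with the population state?
#'
#' The cell's firing rate is computed separately within every high-state and
#' every low-state visit; the cell is accordant when its per-visit high
#' rates exceed its low rates by a one-sided Wilcoxon rank-sum test at level
#' `alpha`. A silent cell is never accordant.
#'
#' @param counts integer vector of the cell's per-frame spike counts.
#' @param segmentation a [segment_states()] result.
#' @param alpha test level.
#' @return list: `accordant` (logical), `p` (test p-value), `rate_ratio`
#'   (overall high-state over low-state rate).
#' @export
cell_accordance <- function(counts, segmentation, alpha = 0.05) {
  stopifnot(inherits(segmentation, "state_segmentation"))
  fs <- segmentation$frame_rate
  lab <- segmentation$frame_labels
  if (length(counts) != length(lab)) stop("counts/segmentation length mismatch")
  if (sum(counts) == 0) {
    return(list(accordant = FALSE, p = 1, rate_ratio = NA_real_))
  }
  st <- segmentation$states
  visit_rate <- function(i) {
    a <- round(st$start_s[i] * fs) + 1L
    b <- min(a + round(st$duration_s[i] * fs) - 1L, length(counts))
    60 * sum(counts[a:b]) / st$duration_s[i]
  }
  rates <- vapply(seq_len(nrow(st)), visit_rate, numeric(1)) # spikes/min
  hi <- st$label == "high"
  if (!any(hi) || !all(c(sum(st$duration_s[hi]), sum(st$duration_s[!hi])) >= 10)) {
    return(list(accordant = FALSE, p = NA_real_, rate_ratio = NA_real_))
  }
  p <- suppressWarnings(
    stats::wilcox.test(rates[hi], rates[!hi], alternative = "greater")$p.value
  )
  hr <- 60 * sum(counts[lab == "high"]) / (sum(lab == "high") / fs)
  lr <- 60 * sum(counts[lab == "low"]) / (sum(lab == "low") / fs)
  list(
    accordant = is.finite(p) && p < alpha,
    p = p,
    rate_ratio = if (lr > 0) hr / lr else Inf
  )
}

#' Aggregate state/accordance results across populations
#'
#' @param populations list, one entry per population, each a list with at
#'   least `bimodal` (logical) and optionally `segmentation` (a
#'   [segment_states()] result) and `accordant` (logical per cell).
#' @return one-row data.frame: percentage of bimodal populations, mean +/-
#'   SEM percentage of accordant cells, and mean high/low durations and
#'   rates across bimodal populations.
#' @export
population_summary <- function(populations) {
  n <- length(populations)
  if (n == 0) stop("no populations supplied")
  bi <- vapply(populations, function(p) isTRUE(p$bimodal), logical(1))
  pct_acc <- vapply(populations, function(p) {
    if (isTRUE(p$bimodal) && !is.null(p$accordant)) {
      100 * mean(p$accordant)
    } else {
      NA_real_
    }
  }, numeric(1))
  seg_stat <- function(field) {
    v <- vapply(populations, function(p) {
      if (isTRUE(p$bimodal) && !is.null(p$segmentation)) {
        p$segmentation[[field]]
      } else {
        NA_real_
      }
    }, numeric(1))
    v[is.finite(v)]
  }
  msem <- function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  }
  acc <- msem(pct_acc[is.finite(pct_acc)])
  hd <- msem(seg_stat("mean_high_s")); ld <- msem(seg_stat("mean_low_s"))
  hr <- msem(seg_stat("high_rate_spm")); lr <- msem(seg_stat("low_rate_spm"))
  data.frame(
    n_populations = n,
    pct_bimodal = 100 * mean(bi),
    pct_accordant_mean = acc[1], pct_accordant_sem = acc[2],
    high_duration_s_mean = hd[1], high_duration_s_sem = hd[2],
    low_duration_s_mean = ld[1], low_duration_s_sem = ld[2],
    high_rate_spm_mean = hr[1], high_rate_spm_sem = hr[2],
    low_rate_spm_mean = lr[1], low_rate_spm_sem = lr[2]
  )
}
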