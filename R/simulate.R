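#' Configuration for a synthetic population recording
#'
#' Describes a population of neurons whose firing alternates between a low
#' and a high activity state (exponentially distributed dwell times, i.e. a
#' two-state continuous-time Markov chain discretized to frames), with
#' population-wide synchrony events superimposed, convolved with a
#' GCaMP6f-like unitary kernel and corrupted by slow baseline drift and
#' white noise. Defaults mirror a typical prefrontal two-photon session:
#' 7 Hz acquisition, 1500 frames (3.6 min).
#'
#' @param n_cells number of simultaneously recorded cells.
#' @param frame_rate acquisition rate, Hz.
#' @param n_frames recording length in frames.
#' @param low_rate,high_rate firing rates in the low/high state, spikes/min.
#' @param mean_low_duration,mean_high_duration mean state dwell times, s.
#' @param accordant_fraction fraction of cells following the population
#'   state; the rest fire at the state-occupancy-weighted average rate.
#' @param sync_event_rate rate of population synchrony events, events/min.
#' @param sync_participation fraction of cells receiving a spike in each
#'   synchrony event.
#' @param kernel a [ca_kernel()] used for the spike-to-fluorescence forward
#'   model.
#' @param drift_amplitude total peak amplitude of the slow baseline drift,
#'   dF/F fraction (sum of 3 sinusoids with random sub-`drift_max_freq`
#'   frequencies and phases).
#' @param drift_max_freq upper edge of the drift band, Hz (< 0.05).
#' @param noise_sd white noise SD, dF/F fraction.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return validated list of class `simulation_config`.
#' @seealso [preset_config()], [simulate_population()]
#' @export
simulation_config <- function(n_cells = 40,
                              frame_rate = 7,
                              n_frames = 1500,
                              low_rate = 1.69,
                              high_rate = 21.37,
                              mean_low_duration = 16.96,
                              mean_high_duration = 2.26,
                              accordant_fraction = 0.85,
                              sync_event_rate = 3.95,
                              sync_participation = 0.31,
                              kernel = ca_kernel(0.215202, 0.200, 0.390),
                              drift_amplitude = 0.05,
                              drift_max_freq = 0.03,
                              noise_sd = 0.03,
                              seed = NULL) {
  cfg <- list(
    n_cells = n_cells, frame_rate = frame_rate, n_frames = n_frames,
    low_rate = low_rate, high_rate = high_rate,
    mean_low_duration = mean_low_duration,
    mean_high_duration = mean_high_duration,
    accordant_fraction = accordant_fraction,
    sync_event_rate = sync_event_rate,
    sync_participation = sync_participation,
    kernel = kernel, drift_amplitude = drift_amplitude,
    drift_max_freq = drift_max_freq, noise_sd = noise_sd, seed = seed
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  need_pos <- c(
    "frame_rate", "n_frames", "mean_low_duration", "mean_high_duration"
  )
  need_nonneg <- c(
    "low_rate", "high_rate", "sync_event_rate", "drift_amplitude", "noise_sd"
  )
  need_frac <- c("accordant_fraction", "sync_participation")
  for (f in c(need_pos, need_nonneg, need_frac)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("config field '%s' must be a finite number", f))
    }
  }
  for (f in need_pos) {
    if (cfg[[f]] <= 0) stop(sprintf("config field '%s' must be > 0", f))
  }
  for (f in need_nonneg) {
    if (cfg[[f]] < 0) stop(sprintf("config field '%s' must be >= 0", f))
  }
  for (f in need_frac) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("config field '%s' must lie in [0, 1]", f))
    }
  }
  if (cfg$n_cells < 1) stop("config field 'n_cells' must be >= 1")
  if (cfg$drift_max_freq <= 0 || cfg$drift_max_freq >= 0.05) {
    stop("config field 'drift_max_freq' must lie in (0, 0.05) Hz")
  }
  if (!inherits(cfg$kernel, "ca_kernel")) {
    stop("config field 'kernel' must be a ca_kernel object")
  }
  if (!is.null(cfg$seed) &&
    (!is.numeric(cfg$seed) || !is.finite(cfg$seed))) {
    stop("config field 'seed' must be a finite integer or NULL")
  }
  structure(cfg, class = "simulation_config")
}

#' Preset configurations mirroring the reported activity regimes
#'
#' Returns a [simulation_config()] whose state rates and durations,
#' synchrony event rate and participation, accordant fraction and unitary
#' kernel equal the group means reported for sham- and hAPP-injected mice at
#' 1 and 6 months post-injection.
#'
#' @param group_label one of `"sham_1mpi"`, `"hAPP_1mpi"`, `"sham_6mpi"`,
#'   `"hAPP_6mpi"`.
#' @param ... overrides passed on to [simulation_config()] (e.g. `n_cells`,
#'   `seed`).
#' @return a `simulation_config` with `group_label` attached.
#' @examples
#' preset_config("sham_6mpi")$mean_low_duration # 16.96
#' @export
preset_config <- function(group_label, ...) {
  presets <- list(
    sham_1mpi = list(
      low_rate = 5.22, high_rate = 20.16,
      mean_low_duration = 5.2, mean_high_duration = 3.32,
      sync_event_rate = 1.27, sync_participation = 0.5066,
      accordant_fraction = 0.7391,
      kernel = ca_kernel(0.215202, 0.200, 0.390)
    ),
    hAPP_1mpi = list(
      low_rate = 5.4, high_rate = 23.88,
      mean_low_duration = 6.5, mean_high_duration = 3.6,
      sync_event_rate = 2.08, sync_participation = 0.5186,
      accordant_fraction = 0.7368,
      kernel = ca_kernel(0.217686, 0.160, 0.350)
    ),
    sham_6mpi = list(
      low_rate = 1.69, high_rate = 21.37,
      mean_low_duration = 16.96, mean_high_duration = 2.26,
      sync_event_rate = 3.95, sync_participation = 0.3118,
      accordant_fraction = 0.8461,
      kernel = ca_kernel(0.215057, 0.190, 0.370)
    ),
    hAPP_6mpi = list(
      low_rate = 5.3, high_rate = 28.5,
      mean_low_duration = 9.96, mean_high_duration = 3.17,
      sync_event_rate = 0.72, sync_participation = 0.414,
      accordant_fraction = 0.85,
      kernel = ca_kernel(0.222633, 0.180, 0.370)
    )
  )
  if (!group_label %in% names(presets)) {
    stop(sprintf(
      "unknown group label '%s' (expected one of %s)",
      group_label, paste(names(presets), collapse = ", ")
    ))
  }
  args <- utils::modifyList(presets[[group_label]], list(...))
  cfg <- do.call(simulation_config, args)
  attr(cfg, "group_label") <- group_label
  cfg
}

#' Simulate a ground-truthed population recording
#'
#' Draws an alternating high/low state sequence with exponential dwell
#' times, fires accordant cells as inhomogeneous Poisson processes at the
#' state rates and non-accordant cells at the realized occupancy-weighted
#' average rate, superimposes synchrony events (a Poisson process in time,
#' each adding one spike to a random `sync_participation` fraction of cells
#' in a single frame), convolves with the unitary kernel and adds per-cell
#' sinusoidal drift plus white noise.
#'
#' @param config a [simulation_config()].
#' @return list with components
#'   \describe{
#'     \item{recording}{a [ca_recording()] of dF/F traces.}
#'     \item{ground_truth}{list: `spikes` (frames x cells integer matrix),
#'       `state` (per-frame `"high"`/`"low"`), `sync_frames` (frame indices
#'       of synchrony events), `accordant` (logical per cell),
#'       `state_segments` (data.frame of the generating dwell segments).}
#'   }
#' @export
simulate_population <- function(config) {
  cfg <- validate_simulation_config(config)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  fs <- cfg$frame_rate
  n <- cfg$n_frames
  nc <- cfg$n_cells
  duration_s <- n / fs

  # --- state sequence: alternating exponential dwell times ---
  p_high0 <- cfg$mean_high_duration /
    (cfg$mean_high_duration + cfg$mean_low_duration)
  state0 <- if (stats::runif(1) < p_high0) "high" else "low"
  labels <- character(0)
  durs <- numeric(0)
  total <- 0
  cur <- state0
  while (total < duration_s) {
    m <- if (cur == "high") cfg$mean_high_duration else cfg$mean_low_duration
    d <- stats::rexp(1, rate = 1 / m)
    labels <- c(labels, cur)
    durs <- c(durs, d)
    total <- total + d
    cur <- if (cur == "high") "low" else "high"
  }
  bounds <- cumsum(durs)
  frame_t <- (seq_len(n) - 0.5) / fs
  state <- labels[findInterval(frame_t, c(0, bounds), rightmost.closed = TRUE)]

  # --- spikes ---
  accordant <- rep(FALSE, nc)
  n_acc <- round(cfg$accordant_fraction * nc)
  if (n_acc > 0) accordant[sample.int(nc, n_acc)] <- TRUE
  occ_high <- mean(state == "high")
  rate_state <- ifelse(state == "high", cfg$high_rate, cfg$low_rate) # spikes/min
  rate_avg <- occ_high * cfg$high_rate + (1 - occ_high) * cfg$low_rate
  lam_state <- rate_state / 60 / fs # expected spikes per frame
  lam_avg <- rate_avg / 60 / fs
  spikes <- matrix(0L, nrow = n, ncol = nc)
  for (j in seq_len(nc)) {
    lam <- if (accordant[j]) lam_state else rep(lam_avg, n)
    spikes[, j] <- stats::rpois(n, lam)
  }

  # --- synchrony events ---
  n_sync <- stats::rpois(1, cfg$sync_event_rate * duration_s / 60)
  sync_frames <- integer(0)
  if (n_sync > 0 && cfg$sync_participation > 0) {
    sync_frames <- sort(sample.int(n, min(n_sync, n)))
    m <- ceiling(cfg$sync_participation * nc)
    for (f in sync_frames) {
      cells <- sample.int(nc, m)
      spikes[f, cells] <- spikes[f, cells] + 1L
    }
  }

  # --- forward model: kernel convolution + drift + noise ---
  kw <- kernel_waveform(cfg$kernel, fs)
  traces <- matrix(0, nrow = n, ncol = nc)
  for (j in seq_len(nc)) {
    if (any(spikes[, j] > 0)) {
      conv <- stats::convolve(spikes[, j], rev(kw), type = "open")[seq_len(n)]
      traces[, j] <- conv
    }
    if (cfg$drift_amplitude > 0) {
      freqs <- stats::runif(3, 0.001, cfg$drift_max_freq)
      phases <- stats::runif(3, 0, 2 * pi)
      t_s <- (seq_len(n) - 1) / fs
      drift <- rowSums(vapply(
        1:3,
        function(i) sin(2 * pi * freqs[i] * t_s + phases[i]),
        numeric(n)
      )) * (cfg$drift_amplitude / 3)
      traces[, j] <- traces[, j] + drift
    }
    if (cfg$noise_sd > 0) {
      traces[, j] <- traces[, j] + stats::rnorm(n, 0, cfg$noise_sd)
    }
  }
  colnames(traces) <- paste0("cell_", seq_len(nc) - 1L)

  rec <- ca_recording(
    traces = traces, frame_rate = fs,
    population_id = "sim",
    group_label = attr(config, "group_label") %||% "custom"
  )
  list(
    recording = rec,
    ground_truth = list(
      spikes = spikes,
      state = state,
      sync_frames = sync_frames,
      accordant = accordant,
      state_segments = data.frame(
        label = labels,
        start_s = c(0, bounds[-length(bounds)]),
        duration_s = durs
      )
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
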