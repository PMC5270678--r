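#' Population recording container
#'
#' @param traces numeric matrix, frames x cells, dF/F fractions.
#' @param frame_rate Hz.
#' @param population_id identifier.
#' @param group_label experimental group identifier.
#' @return object of class `ca_recording` with fields `traces`,
#'   `frame_rate`, `n_frames`, `duration_s`, `population_id`,
#'   `group_label`.
#' @export
ca_recording <- function(traces, frame_rate, population_id = "pop",
                         group_label = "none") {
  traces <- as.matrix(traces)
  if (!is.numeric(traces) || any(!is.finite(traces))) {
    stop("traces must be a finite numeric matrix")
  }
  if (nrow(traces) < 2) stop("recording needs >= 2 frames")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  if (is.null(colnames(traces))) {
    colnames(traces) <- paste0("cell_", seq_len(ncol(traces)) - 1L)
  }
  structure(
    list(
      traces = traces,
      frame_rate = frame_rate,
      n_frames = nrow(traces),
      duration_s = nrow(traces) / frame_rate,
      population_id = population_id,
      group_label = group_label
    ),
    class = "ca_recording"
  )
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf(
    "calcium recording '%s' (%s): %d cells x %d frames @ %g Hz = %.1f min\n",
    x$population_id, x$group_label, ncol(x$traces), x$n_frames,
    x$frame_rate, x$duration_s / 60
  ))
  invisible(x)
}

#' Read dF/F traces from CSV
#'
#' Expects a header `frame, cell_0, cell_1, ...`; the frame column is
#' 0-based. Non-numeric cells and NAs are rejected with the offending cells
#' named.
#'
#' @param path CSV file.
#' @param frame_rate Hz (not stored in the CSV).
#' @param population_id,group_label identifiers for the returned recording.
#' @return a [ca_recording()].
#' @export
read_traces <- function(path, frame_rate, population_id = NULL,
                        group_label = "none") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop(sprintf("%s: expected header 'frame, cell_*' and >= 1 data row", path))
  }
  if (names(df)[1] != "frame") {
    stop(sprintf("%s: first column must be 'frame', found '%s'", path, names(df)[1]))
  }
  cells <- df[, -1, drop = FALSE]
  bad <- vapply(cells, function(v) !is.numeric(v) || anyNA(v), logical(1))
  if (any(bad)) {
    stop(sprintf(
      "%s: non-numeric or missing values in column(s) %s",
      path, paste(names(cells)[bad], collapse = ", ")
    ))
  }
  ca_recording(
    traces = as.matrix(cells), frame_rate = frame_rate,
    population_id = population_id %||% sub("\\.csv$", "", basename(path)),
    group_label = group_label
  )
}

#' Write dF/F traces to CSV
#'
#' Inverse of [read_traces()]: header `frame, cell_*`, 0-based frame
#' indices, dF/F as decimal fractions.
#'
#' @param recording a [ca_recording()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(recording, path) {
  stopifnot(inherits(recording, "ca_recording"))
  df <- data.frame(frame = seq_len(recording$n_frames) - 1L, recording$traces,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation and its ground truth to a directory
#'
#' Traces as `traces.csv` (frame, cell_*), ground-truth spikes as
#' `spikes.csv` ((cell, frame, count) triplets, 0-based), the state sequence
#' as `states.csv`, and the configuration as a flat `config.txt`
#' (key=value).
#'
#' @param sim result of [simulate_population()].
#' @param config the [simulation_config()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_traces(sim$recording, file.path(dir, "traces.csv"))
  sp <- sim$ground_truth$spikes
  nz <- which(sp > 0, arr.ind = TRUE)
  utils::write.csv(
    data.frame(
      cell = nz[, "col"] - 1L, frame = nz[, "row"] - 1L,
      count = sp[nz]
    )[order(nz[, "col"], nz[, "row"]), ],
    file.path(dir, "spikes.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    data.frame(
      frame = seq_along(sim$ground_truth$state) - 1L,
      state = sim$ground_truth$state
    ),
    file.path(dir, "states.csv"),
    row.names = FALSE
  )
  scalars <- config[!vapply(config, is.object, logical(1))]
  scalars$kernel_amplitude <- config$kernel$amplitude
  scalars$kernel_tau_rise <- config$kernel$tau_rise
  scalars$kernel_tau_decay <- config$kernel$tau_decay
  scalars <- scalars[!vapply(scalars, is.null, logical(1))]
  writeLines(
    paste0(names(scalars), "=", vapply(scalars, format, character(1))),
    file.path(dir, "config.txt")
  )
  message(sprintf(
    "simulation written to %s (seed %s)", normalizePath(dir),
    format(config$seed %||% "none")
  ))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis stages, with range validation.
#'
#' @param frame_rate Hz.
#' @param cutoff_hz baseline-correction cutoff (drift scale), Hz.
#' @param k_sigma transient detection threshold in noise-SD units.
#' @param min_duration_s minimal transient duration, s.
#' @param smooth_sigma_s Gaussian SD for the population activity, s.
#' @param min_state_s minimal state duration, s.
#' @param bin_width_s synchrony bin width, s; default one frame interval.
#' @param n_surrogates surrogate count for the synchrony null.
#' @param alpha significance level (synchrony and accordance).
#' @param merge_gap peak merge gap, bins.
#' @param valley_depth bimodality valley criterion (relative dip).
#' @param seed integer seed for the surrogate draws (and simulation when
#'   the pipeline simulates its input).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(frame_rate = 7, cutoff_hz = 0.05, k_sigma = 3,
                       min_duration_s = 2 / frame_rate, smooth_sigma_s = 0.5,
                       min_state_s = 2 / frame_rate,
                       bin_width_s = 1 / frame_rate, n_surrogates = 1000,
                       alpha = 0.05, merge_gap = 1, valley_depth = 0.2,
                       seed = 1L) {
  cfg <- list(
    frame_rate = frame_rate, cutoff_hz = cutoff_hz, k_sigma = k_sigma,
    min_duration_s = min_duration_s, smooth_sigma_s = smooth_sigma_s,
    min_state_s = min_state_s, bin_width_s = bin_width_s,
    n_surrogates = n_surrogates, alpha = alpha, merge_gap = merge_gap,
    valley_depth = valley_depth, seed = seed
  )
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("config field '%s' must be a finite number", f))
    }
  }
  if (frame_rate <= 0) stop("config field 'frame_rate' must be > 0")
  if (cutoff_hz <= 0 || cutoff_hz >= frame_rate / 2) {
    stop("config field 'cutoff_hz' must lie in (0, frame_rate/2)")
  }
  if (k_sigma <= 0) stop("config field 'k_sigma' must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("config field 'alpha' must lie in (0, 1)")
  if (n_surrogates < 100) stop("config field 'n_surrogates' must be >= 100")
  if (bin_width_s < 1 / frame_rate) {
    stop("config field 'bin_width_s' must be >= one frame interval")
  }
  structure(cfg, class = "run_config")
}

#' Analyse one population recording end-to-end
#'
#' Baseline correction, transient detection, unitary-transient selection and
#' kernel fitting (falling back to `kernel` when supplied), deconvolution,
#' state segmentation with per-cell accordance, and surrogate-tested
#' synchrony.
#'
#' @param recording a [ca_recording()].
#' @param config a [run_config()].
#' @param kernel optional [ca_kernel()]; when `NULL` the kernel is fitted
#'   from the recording's unitary transients.
#' @return list with `transients`, `transient_stats`, `kernel`, `spikes`
#'   (frames x cells), `rates_spm`, `bimodal`, `threshold`, `segmentation`,
#'   `accordant`, `synchrony`, `recording`.
#' @export
analyze_population <- function(recording, config = run_config(),
                               kernel = NULL) {
  stopifnot(inherits(recording, "ca_recording"))
  fs <- recording$frame_rate
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf(
        "pipeline stage '%s' failed for population '%s': %s",
        name, recording$population_id, conditionMessage(e)
      ), call. = FALSE)
    })
  }

  corrected <- stage("baseline", {
    apply(recording$traces, 2, correct_baseline,
      frame_rate = fs, cutoff = config$cutoff_hz
    )
  })
  transients <- stage("transients", {
    detect_transients_population(corrected, fs,
      k_sigma = config$k_sigma, min_duration = config$min_duration_s
    )
  })
  tstats <- transient_statistics(transients, recording$duration_s / 60)

  if (is.null(kernel)) {
    kernel <- stage("kernel", {
      uni <- select_unitary_transients(transients)
      w <- mean_transient_waveform(corrected, uni, fs)
      fit_kernel(w, fs)
    })
  }

  spikes <- stage("deconvolve", deconvolve_population(corrected, kernel, fs))
  rates <- apply(spikes, 2, spike_rate, frame_rate = fs)

  act <- stage("states", population_activity(spikes, fs, config$smooth_sigma_s))
  thr <- compute_state_threshold(act, valley_depth = config$valley_depth)
  segmentation <- NULL
  accordant <- NULL
  if (thr$bimodal) {
    segmentation <- stage(
      "states",
      segment_states(act, thr$threshold, config$min_state_s)
    )
    accordant <- vapply(
      seq_len(ncol(spikes)),
      function(j) cell_accordance(spikes[, j], segmentation, config$alpha)$accordant,
      logical(1)
    )
  }

  synchrony <- stage("synchrony", {
    analyze_synchrony(spikes, fs,
      bin_width = config$bin_width_s, n_surrogates = config$n_surrogates,
      alpha = config$alpha, merge_gap = config$merge_gap, seed = config$seed
    )
  })

  list(
    transients = transients, transient_stats = tstats, kernel = kernel,
    spikes = spikes, rates_spm = rates, bimodal = thr$bimodal,
    threshold = thr$threshold, segmentation = segmentation,
    accordant = accordant, synchrony = synchrony, recording = recording
  )
}

#' Run the full pipeline over one or more populations
#'
#' Accepts recordings (or preset labels, which are simulated with seeds
#' derived from `config$seed`), analyses each population, aggregates
#' group-level tables and, when two or more groups are present, compares
#' spikes/min across groups with Kruskal-Wallis. When `outdir` is given,
#' per-population tables, group summaries and a JSON run manifest are
#' written; the run is deterministic given the seed.
#'
#' @param populations list whose elements are [ca_recording()] objects or
#'   preset labels understood by [preset_config()].
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @param n_cells cells per simulated population (presets only).
#' @return list: `populations` (per-population [analyze_population()]
#'   results), `summary` (from [population_summary()]), `group_rates`,
#'   `group_synchrony` (data.frames), `kw` (Kruskal-Wallis on spikes/min
#'   across groups, or `NULL`).
#' @export
run_pipeline <- function(populations, config = run_config(), outdir = NULL,
                         n_cells = 40) {
  stopifnot(length(populations) >= 1)
  recs <- lapply(seq_along(populations), function(i) {
    p <- populations[[i]]
    if (inherits(p, "ca_recording")) {
      return(p)
    }
    if (is.character(p) && length(p) == 1) {
      cfg <- preset_config(p, n_cells = n_cells, seed = config$seed + 1000L * i)
      sim <- simulate_population(cfg)
      rec <- sim$recording
      rec$population_id <- sprintf("%s_%02d", p, i)
      return(rec)
    }
    stop(sprintf("populations[[%d]] is neither a recording nor a preset label", i))
  })

  results <- lapply(recs, analyze_population, config = config)
  names(results) <- vapply(recs, function(r) r$population_id, character(1))

  groups <- vapply(recs, function(r) r$group_label, character(1))
  group_rates <- data.frame(
    group = rep(groups, vapply(results, function(r) length(r$rates_spm), integer(1))),
    rate_spm = unlist(lapply(results, function(r) r$rates_spm)),
    row.names = NULL
  )
  group_synchrony <- data.frame(
    population = names(results),
    group = groups,
    peaks_per_min = vapply(results, function(r) r$synchrony$peaks_per_min, numeric(1)),
    mean_peak_coactivity_pct = vapply(
      results,
      function(r) r$synchrony$mean_peak_coactivity_pct, numeric(1)
    ),
    synchronous = vapply(results, function(r) r$synchrony$synchronous, logical(1)),
    row.names = NULL
  )
  summary_tab <- population_summary(results)

  kw <- NULL
  if (length(unique(groups)) >= 2) {
    kw <- kruskal_wallis(split(group_rates$rate_spm, group_rates$group),
      p_method = "asymptotic"
    )
  }

  out <- list(
    populations = results, summary = summary_tab,
    group_rates = group_rates, group_synchrony = group_synchrony, kw = kw
  )
  if (!is.null(outdir)) write_pipeline_outputs(out, config, outdir)
  out
}

write_pipeline_outputs <- function(out, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  for (id in names(out$populations)) {
    r <- out$populations[[id]]
    if (nrow(r$transients)) wcsv(r$transients, sprintf("%s_transients.csv", id))
    nz <- which(r$spikes > 0, arr.ind = TRUE)
    wcsv(
      data.frame(cell = nz[, "col"] - 1L, frame = nz[, "row"] - 1L, count = r$spikes[nz]),
      sprintf("%s_spikes.csv", id)
    )
    if (!is.null(r$segmentation)) {
      wcsv(r$segmentation$states, sprintf("%s_states.csv", id))
    }
    wcsv(
      data.frame(
        bin_s = (seq_along(r$synchrony$coactive_fraction) - 1) * r$synchrony$bin_s,
        coactive_fraction = r$synchrony$coactive_fraction,
        significant = r$synchrony$coactive_fraction > r$synchrony$sig_threshold
      ),
      sprintf("%s_synchrony.csv", id)
    )
  }
  kernels <- do.call(rbind, lapply(names(out$populations), function(id) {
    k <- out$populations[[id]]$kernel
    data.frame(
      population = id, amplitude_dff_pct = 100 * k$amplitude,
      tau_rise_ms = 1000 * k$tau_rise, tau_decay_ms = 1000 * k$tau_decay
    )
  }))
  wcsv(kernels, "kernels.csv")
  wcsv(out$summary, "population_summary.csv")
  wcsv(out$group_synchrony, "group_synchrony.csv")
  manifest <- list(
    package = "casync",
    version = as.character(utils::packageVersion("casync")),
    r_version = as.character(getRversion()),
    config = unclass(config),
    populations = names(out$populations),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(outdir)
}
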