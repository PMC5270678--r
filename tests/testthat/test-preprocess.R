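fs <- 7
n <- 1500
t_s <- (0:(n - 1)) / fs

test_that("baseline correction removes DC and sub-cutoff drift", {
  expect_equal(correct_baseline(rep(0.30, n), fs), rep(0, n))

  # pure 0.01 Hz sinusoid, amplitude 0.2: residual amplitude < 0.02,
  # checked both in the time domain and with a discrete Fourier oracle
  x <- 0.2 * sin(2 * pi * 0.01 * t_s)
  y <- correct_baseline(x, fs)
  expect_lt(max(abs(y)), 0.02)
  expect_lt(dft_power(y, 0.01, fs) / dft_power(x, 0.01, fs), 0.1)

  # >= 90% power attenuation across the drift band
  for (f in c(0.005, 0.02, 0.035, 0.049)) {
    x <- sin(2 * pi * f * t_s)
    y <- correct_baseline(x, fs)
    expect_lt(dft_power(y, f, fs) / dft_power(x, f, fs), 0.1)
  }

  # transient-scale components retained (>= 95% amplitude at 0.5 Hz)
  x <- sin(2 * pi * 0.5 * t_s)
  y <- correct_baseline(x, fs)
  expect_gt(sqrt(dft_power(y, 0.5, fs) / dft_power(x, 0.5, fs)), 0.95)

  # mean of output ~ 0
  set.seed(1)
  z <- correct_baseline(stats::rnorm(n, 0.4, 0.05), fs)
  expect_lt(abs(mean(z)), 1e-12)
})

test_that("baseline correction preserves transient peaks and is idempotent", {
  k <- ca_kernel(0.215, 0.200, 0.390)
  x <- numeric(n)
  w <- kernel_waveform(k, fs)
  x[700 + seq_along(w) - 1] <- w
  y <- correct_baseline(x, fs)
  expect_lt((max(x) - max(y)) / max(x), 0.05)
  expect_equal(correct_baseline(y, fs), y, tolerance = 1e-8)
})

test_that("short traces fall back to mean subtraction with a warning", {
  x <- 0.1 + (1:50) / 500
  expect_warning(y <- correct_baseline(x, fs), "cutoff period")
  expect_equal(y, x - mean(x))
})

test_that("transient detection finds isolated events with correct onsets", {
  k <- ca_kernel(0.215, 0.200, 0.390)
  set.seed(7)
  noise_sd <- max(kernel_waveform(k, fs)) / 10
  x <- stats::rnorm(n, 0, noise_sd)
  w <- kernel_waveform(k, fs)
  for (f in c(300, 300 + round(5 * fs))) x[f + seq_along(w) - 1] <- x[f + seq_along(w) - 1] + w
  tr <- detect_transients(x, fs)
  expect_equal(nrow(tr), 2)
  expect_true(all(diff(tr$onset_frame) > 0))
  expect_lte(abs(tr$onset_frame[1] - 300), 2)
  expect_equal(tr$onset_s, (tr$onset_frame - 1) / fs)
  expect_true(all(tr$amplitude > 0 & tr$duration_s > 0))
  expect_true(all(tr$onset_frame <= tr$peak_frame))
})

test_that("flat or constant traces yield no transients", {
  expect_equal(nrow(detect_transients(numeric(n), fs)), 0)
  expect_equal(nrow(detect_transients(rep(3, n), fs)), 0)
})

test_that("detection count is invariant to a constant offset", {
  set.seed(11)
  x <- stats::rnorm(n, 0, 0.01)
  w <- kernel_waveform(ca_kernel(0.2, 0.2, 0.39), fs)
  x[500 + seq_along(w) - 1] <- x[500 + seq_along(w) - 1] + w
  expect_equal(
    nrow(detect_transients(x, fs)),
    nrow(detect_transients(x + 5, fs))
  )
})

test_that("transient durations scale correctly when resampled at 2x rate", {
  # a steep-edged 2 s bump: threshold crossings are insensitive to the
  # noise floor, so the measured duration should agree across sampling
  # rates to within one frame of the coarser rate
  set.seed(5)
  build <- function(rate) {
    t <- (0:round(100 * rate)) / rate
    x <- ifelse(t >= 40 & t <= 42, 0.3 * sin(pi * (t - 40) / 2)^2, 0)
    x <- x + stats::rnorm(length(x), 0, 0.002)
    detect_transients(x, rate)
  }
  d7 <- build(7)
  d14 <- build(14)
  expect_equal(nrow(d7), 1)
  expect_equal(nrow(d14), 1)
  expect_lte(abs(d7$duration_s - d14$duration_s), 1 / 7 + 1 / 14)
})

test_that("transient statistics compute rates and handle empty input", {
  tr <- data.frame(duration_s = rep(1, 9))
  s <- transient_statistics(tr, 3.6)
  expect_equal(s$rate, 2.5)
  expect_equal(s$n, 9)
  s0 <- transient_statistics(NULL, 3.6)
  expect_equal(s0$rate, 0)
  expect_length(s0$durations_s, 0)
  expect_error(transient_statistics(tr, 0), "positive")
})

test_that("empirical transient rate matches a Poisson oracle", {
  # cells firing sparsely at ~1.5 events/min: detected rate within 3 SE
  k <- ca_kernel(0.215, 0.2, 0.39)
  fs <- 7
  set.seed(21)
  n_cells <- 30
  rate_true <- 1.5
  rates <- vapply(seq_len(n_cells), function(j) {
    cnt <- integer(1500)
    n_ev <- stats::rpois(1, rate_true * 1500 / fs / 60)
    if (n_ev > 0) cnt[sample(1:1400, n_ev)] <- 1L
    x <- trace_with_spikes(cnt, k, fs) + stats::rnorm(1500, 0, 0.01)
    transient_statistics(detect_transients(x, fs), 1500 / fs / 60)$rate
  }, numeric(1))
  total_T <- n_cells * 1500 / fs / 60
  se <- sqrt(rate_true / total_T)
  expect_lt(abs(mean(rates) - rate_true), 3 * se)
})
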