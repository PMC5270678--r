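# Shared fixtures built in code.

group_kernels <- list(
  sham_1mpi = ca_kernel(0.215202, 0.200, 0.390),
  hAPP_1mpi = ca_kernel(0.217686, 0.160, 0.350),
  sham_6mpi = ca_kernel(0.215057, 0.190, 0.370),
  hAPP_6mpi = ca_kernel(0.222633, 0.180, 0.370)
)

# Place unit kernels at given (1-based) frames on a zero trace.
trace_with_spikes <- function(counts, kernel, frame_rate) {
  kw <- kernel_waveform(kernel, frame_rate)
  stats::convolve(counts, rev(kw), type = "open")[seq_along(counts)]
}

# Poisson spike train at a stationary rate (spikes/min).
poisson_counts <- function(n_frames, rate_spm, frame_rate) {
  stats::rpois(n_frames, rate_spm / 60 / frame_rate)
}

# DFT power of x at frequency f (Hz), frame rate fs.
dft_power <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  abs(sum(x * exp(-2i * pi * f * t)))^2
}
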