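---
title: "Analysing spontaneous cortical activity from two-photon calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spontaneous cortical activity from two-photon calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casync)
```

## The problem

Two-photon imaging of a genetically encoded calcium indicator (GCaMP6f)
reports the spiking of tens of cortical neurons simultaneously as per-cell
ΔF/F time series, typically acquired at a few Hz for a few minutes (the
defaults throughout this package are 7 Hz and 1500 frames, i.e. 3.6 min).
Spontaneous activity in such recordings has rich structure on several
timescales: sub-second calcium transients caused by action potentials,
second-scale alternation of the whole population between high- and
low-activity states (ultraslow fluctuations), frame-scale synchronous
firing of a large fraction of cells, and sub-0.05 Hz instrumental drift.

`casync` turns per-cell ΔF/F traces into per-cell firing-rate estimates
and population-level state and synchrony measures:

1. **Baseline correction** removes the slow drift.
2. **Transient detection** finds calcium events and their durations.
3. **Kernel estimation** fits the unitary (single-spike) fluorescence
   response.
4. **Deconvolution** inverts the trace into per-frame spike counts.
5. **State segmentation** thresholds the smoothed population activity
   into high/low epochs and scores per-cell accordance.
6. **Synchrony detection** finds time bins where the coactive fraction of
   cells exceeds a circular-shift surrogate null.
7. **Group statistics** compare conditions nonparametrically.

A ground-truthed simulator generates populations with exactly this
structure so that every stage can be validated against known truth.

## The forward model and its inversion

### Unitary kernel

The single-spike response is an alpha function realized as a difference of
exponentials,

$$ g(t) = A \frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{c(\tau_r, \tau_d)}, $$

where $c$ normalizes the peak so that $A$ is the peak ΔF/F amplitude.
Separate rise and decay constants are used because the classical
single-tau alpha function $t e^{1-t/\tau}$ cannot represent independently
measured rise (~160-200 ms) and decay (~350-390 ms) times. The model is
symmetric under exchanging $\tau_r$ and $\tau_d$ (both the numerator and
$c$ flip sign), so fits are reported in canonical order rather than
failing when the optimizer crosses the diagonal; genuinely equal time
constants are a degenerate boundary and raise an error.

`fit_kernel()` does a Levenberg-Marquardt least-squares fit in
log-parameters with three jittered starts derived from the waveform peak
and half-decay time. On noiseless waveforms sampled at 7 Hz the three
parameters are recovered to machine precision; with noise at 5% of the
amplitude, the median over 50 replicates stays within a few percent.

### Deconvolution

Sampled at the frame interval $\Delta$, the kernel is the impulse response
of an AR(2) process: with $a = e^{-\Delta/\tau_d}$ and
$b = e^{-\Delta/\tau_r}$, the exact inverse of the convolution is the
three-tap filter

$$ \hat c_t = \frac{c}{A(a-b)}\left( y_{t+1} - (a+b)\,y_t + ab\,y_{t-1} \right). $$

Applied to a noiseless trace this returns the generating spike counts
*exactly*, for any spike configuration including overlapping transients —
a property we exploit as a round-trip invariant in the tests. We
considered greedy matched-filter peeling instead, but it provably
misplaces spikes two frames apart (the matched-filter maximum falls
between them, since $2\rho(1) > 1 + \rho(\textrm{2})$ for these kernels at
7 Hz), and a greedy subtraction cannot undo the misplacement; the exact
inverse has no such failure mode.

The inverse filter amplifies high-frequency noise, so integer counts are
obtained by rounding (equivalently: a spike is accepted where the
estimated amplitude exceeds half a unitary kernel) *and* candidate frames
must pass a matched-filter gate — the least-squares amplitude of a single
kernel placed at the frame, whose noise SD is several-fold lower, must
also exceed the same threshold. The gate can never remove a true spike
(at a spike-bearing frame the matched-filter amplitude is at least the
spike count) and therefore leaves the noiseless exactness untouched,
while suppressing isolated false positives away from real activity. A
spike in the final frame produces no fluorescence ($g(0)=0$) and is
unobservable in principle; its count is reported as zero.

### Baseline correction

Drift below 0.05 Hz is estimated with a centered running median over a
window of $1/(3 \cdot \textrm{cutoff})$ seconds (6.7 s by default) and
subtracted. We deliberately use a robust order statistic rather than a
linear filter: a linear high-pass attenuating everything below 0.05 Hz by
≥ 90% power must remove ≥ 68% amplitude over a 0.1 Hz (two-sided) band,
which necessarily costs a 390 ms-decay transient about 5% of its peak
(its spectral mass at DC is area/peak ≈ 0.79 s). The running median
tracks the drift while *ignoring* sparse positive transients entirely:
measured attenuation is > 99% in power across the whole sub-0.05 Hz band,
0.5 Hz components are retained at > 99.5% amplitude, and the peak of an
isolated unitary transient loses < 0.5%. The estimator is idempotent and
leaves a zero-mean trace. Its known limitation is dense activity: when a
cell is active more than ~half of every window the median rides up and
clips signal; the `q` argument selects a lower percentile for such cells.

### Transient detection

A transient is a maximal run of frames above `k_sigma` (default 3) times
the noise SD lasting at least `min_duration` (default 2 frames). The
noise SD is the scaled median absolute deviation, robust to the
transients themselves. Duration is threshold up-crossing to
down-crossing; this makes durations on exponential tails sensitive to the
noise floor at the crossing (jitter ≈ τ/k), which is why duration-based
assertions in the tests use averages over events. The detection threshold
is not specified in the source material for this analysis style; the
`k_sigma` rule is this package's choice and is exposed in the
configuration.

## Population states

The per-frame mean spike count across cells is smoothed with a Gaussian
(SD `sigma`, reflected boundaries, mass-conserving). The probability
density of the smoothed activity is estimated with a Gaussian kernel
density (Scott's-rule bandwidth); a population is *bimodal* when the two
largest density modes are separated by a valley dipping at least 20%
below the lower mode, and the state threshold is the activity value at
the valley minimum (plateau midpoint when flat). Frames above the
threshold are high-state; runs shorter than `min_state_s` are merged into
their neighbours, shortest first. This mirrors the visual
density-threshold procedure used in the field and is fully deterministic;
we intentionally do not fit a hidden Markov model.

Two numerical choices deserve comment:

* **Smoothing width.** `sigma` defaults to 0.5 s. A 1.0 s kernel (FWHM
  2.35 s) is as wide as the shortest reported mean high-state duration
  (2.26 s) and demonstrably erases the bimodality it is supposed to
  reveal, even on ground-truth spike trains. Resolving states close to
  the frame scale requires narrower smoothing, which in turn requires the
  shot noise of more cells: for duration-recovery benchmarks we use
  σ = 0.2 s with 100-cell populations, and the vignette's rule of thumb
  is σ ≲ (shortest expected state)/4 with
  $\sqrt{\lambda_{high}/(N \cdot 2.5\,\sigma f_s)}$ well below the
  high/low activity separation.
* **Valley criterion.** The 20% dip requirement is a deterministic
  surrogate for a formal dip test; it is exposed as `valley_depth`.

A cell is *accordant* with its population when its per-visit firing rates
in high states exceed those in low states by a one-sided Wilcoxon
rank-sum test at α = 0.05 (the source analysis reports the percentage of
accordant cells without defining the criterion; the rank test on
per-visit counts is this package's definition, and a simple
rate-ratio > 1 alternative can be recovered from the reported
`rate_ratio`).

## Synchrony

Coactivity is the fraction of cells with ≥ 1 spike per time bin (default
one frame, ≈ 0.144 s at 7 Hz). The null model destroys cross-cell
alignment while preserving every cell's rate and autostructure: each of
`n_surrogates` (default 1000) surrogates circularly shifts every cell by
an independent uniform offset. Two thresholds are derived:

* `sig_threshold` — the pooled (1 − α) quantile of all surrogate bins;
  exceeding it is significant per bin. On independent populations the
  fraction of bins exceeding it is α up to the discreteness of a count
  statistic (the exceedance is $P(X > \hat q_{1-\alpha})$, which for
  binomial-like coactive counts is slightly below α).
* `peak_threshold` — the (1 − α) quantile of each surrogate's *maximum*
  coactive fraction. Synchrony peaks are recording-level discoveries, and
  this max-statistic threshold is the default for `analyze_synchrony()`:
  a per-bin threshold flags the binomial tail of every co-aligned
  high-activity epoch (dozens of spurious "peaks" per recording in the
  two-state regimes), whereas the max statistic asks for coactivity that
  even the most extreme chance alignment of the cells' own activity
  profiles cannot produce. Both options are exposed via
  `threshold_type`.

Supra-threshold bins at most `merge_gap` (default 1) bins apart form one
peak, timed at its maximal bin. A population "exhibits synchronous
activity" when it has at least one peak.

## The simulator

`simulate_population()` generates the structure the analysis assumes:

* a two-state continuous-time Markov chain (exponential dwell times with
  the configured means) discretized to frames;
* *accordant* cells (a configurable fraction) firing as inhomogeneous
  Poisson processes at the low/high state rates; the remaining cells fire
  at the realized occupancy-weighted average rate, making them
  rate-matched so accordance detection cannot cheat on total rate;
* synchrony events as a uniform Poisson process in time (independent of
  the state sequence, so the synchrony benchmark does not hinge on state
  segmentation), each adding one spike to a random
  `ceiling(sync_participation * n_cells)` subset of cells in one frame;
* linear convolution with the unitary kernel (one kernel per spike,
  uniform amplitudes — matching the linearity assumed by the
  deconvolution);
* per-cell drift as the sum of 3 sinusoids with random phases and
  frequencies uniform in (0.001, `drift_max_freq`) Hz, spanning the band
  the baseline correction must remove, plus white Gaussian noise.

`preset_config()` parameterizes four regimes with the group means
reported for sham- and hAPP-injected mice at 1 and 6 months
post-injection: state rates and durations, synchrony event rates and
participations, accordant fractions and the four group kernel estimates. The presets are
the study conditions of the validation suite; they are not tuning knobs.

What the simulator does *not* emulate: pixel-level imaging (no point
spread function, motion, or neuropil contamination), indicator
nonlinearity and saturation at bursts, cell-to-cell kernel variability,
and any coupling between synchrony events and high states (the real
system may well synchronize preferentially at state onsets — the
generator keeps them independent, and this is configurable through
`sync_event_rate` itself). Passing the validation suite therefore
demonstrates correctness of the *algorithms* under the stated generative
model, not robustness to every artifact of real recordings.

## Validation problem sizes

The test-suite and acceptance benchmarks use these problem sizes, chosen
as the smallest that make the statistical assertions stable:

* kernel recovery: 18-sample waveforms, 50 noise replicates per group
  kernel;
* deconvolution: 1500-frame traces; exactness at 30 spikes/min over 20
  cells; noisy accuracy over 50 cells per regime (noise SD = 10% of the
  kernel amplitude);
* state recovery: three 100-cell, 12 000-frame (~28.6 min) simulations of
  the sham 6 mpi regime, > 300 state visits pooled, synchrony events
  disabled to isolate the segmentation stage (uniformly placed events
  punch one-frame population spikes into low states and would bias the
  measured dwell times of *both* true and spurious states);
* synchrony: 100 independent 40-cell populations for the calibration
  check, 200-300 surrogates per null in the tests (1000 by default in the
  API);
* group contrast: 8 seeds x (4 sham + 4 hAPP) populations x 40 cells,
  full pipeline including per-recording kernel fits.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(n_surrogates = 300, seed = 1)
res <- run_pipeline(
  list("sham_6mpi", "sham_6mpi", "hAPP_6mpi", "hAPP_6mpi"),
  config = cfg, n_cells = 40
)
aggregate(rate_spm ~ group, res$group_rates, median)
res$group_synchrony
res$kw$p.value
```

The hAPP regime shows the higher median firing rate, the lower synchrony
peak rate and the higher coactive fraction at its peaks, with the
Kruskal-Wallis comparison of per-cell rates strongly significant — the
directional pattern the presets encode.

## Known limitations

* Per-recording kernel fits average waveforms aligned at the *detection
  onset*, which jitters by a frame relative to the true spike; the fitted
  amplitude is biased low and the rise time is poorly constrained at 7 Hz.
  Group comparisons of deconvolved rates are unaffected (the bias is
  shared), but absolute rate estimates are more accurate when the kernel
  is supplied (`analyze_population(..., kernel = )`).
* Sub-frame spike timing is deliberately not inferred at 7 Hz sampling.
* The running-median baseline assumes activity is sparse within its
  window; tonic cells need a lower `q`.
* Bimodality detection is conservative for regimes whose high/low rates
  differ by less than ~4-fold in 3.6-min recordings.
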