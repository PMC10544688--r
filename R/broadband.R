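#' Simulate a broadband voltage snippet with planted spike waveforms
#'
#' White Gaussian noise at a stated RMS with a stereotyped negative-going
#' spike waveform inserted at each planted sample index. The waveform's
#' largest (most negative) deflection occurs exactly at the planted index, so
#' a threshold-crossing extractor should recover each event within a sample.
#' Overlapping waveforms are rejected at generation, which keeps extractor
#' scoring unambiguous.
#'
#' @param spike_times Integer sample indices (1-based) of planted spikes.
#' @param n_samples Total snippet length in samples.
#' @param noise_rms Noise root-mean-square amplitude (same units as
#'   `spike_amp`, nominally microvolts).
#' @param spike_amp Peak (trough) amplitude of each planted spike; must be
#'   negative.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz (default 30000).
#' @return A `broadband_snippet`: list with `trace`, `fs`,
#'   `planted_spike_times`, `noise_rms`, `spike_amp`.
#' @export
simulate_broadband <- function(spike_times, n_samples, noise_rms, spike_amp,
                               seed, fs = 30000) {
  spike_times <- as.integer(spike_times)
  if (spike_amp >= 0) stop("spike_amp must be negative", call. = FALSE)
  if (noise_rms < 0) stop("noise_rms must be >= 0", call. = FALSE)
  wf <- spike_waveform(spike_amp)
  L <- length(wf)
  if (length(spike_times)) {
    if (any(spike_times < 1 | spike_times + L - 1L > n_samples)) {
      stop("spike times out of range for the waveform length", call. = FALSE)
    }
    if (length(spike_times) > 1 && min(diff(sort(spike_times))) < L) {
      stop("planted spike waveforms overlap; space spikes by >= ", L,
           " samples", call. = FALSE)
    }
  }
  with_local_seed(seed, {
    trace <- stats::rnorm(n_samples, sd = noise_rms)
    for (s in spike_times) {
      idx <- s + seq_len(L) - 1L
      trace[idx] <- trace[idx] + wf
    }
    structure(list(trace = trace, fs = fs,
                   planted_spike_times = sort(spike_times),
                   noise_rms = noise_rms, spike_amp = spike_amp),
              class = "broadband_snippet")
  })
}

# Stereotyped extracellular-like waveform: instantaneous trough at sample 1
# (so detection time equals the planted index), exponential recovery with a
# small positive overshoot; ~1 ms at 30 kHz.
spike_waveform <- function(amp, n = 30L) {
  t <- seq_len(n) - 1L
  w <- amp * exp(-t / 5) - 0.25 * amp * exp(-(t - 8)^2 / 18)
  w[1] <- amp   # trough exactly at the planted sample
  w
}

#' @export
print.broadband_snippet <- function(x, ...) {
  cat(sprintf("<broadband_snippet> %d samples @ %g Hz, %d planted spikes, noise RMS %g\n",
              length(x$trace), x$fs, length(x$planted_spike_times),
              x$noise_rms))
  invisible(x)
}
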