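# Shared fixtures, all built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# An observer that responds correctly on essentially every trial:
# enormous sensitivity and zero lapse drive the Weibull arbitrarily
# close to 1 at any representable contrast.
ideal_observer <- function() {
  observer_model(
    csf_strong = true_csf(
      peak_gain = 1e9, peak_sf = 2, log_bandwidth = 5,
      low_freq_truncation = 1
    ),
    lapse_rate = 0
  )
}

default_observer <- function(...) observer_model(...)

# Independent least-squares oracle for harmonic coefficients: plain QR
# projection onto the sinusoid design, bypassing the recursive filter.
ols_coefficients <- function(x, f_targets, sampling_rate) {
  n <- length(x)
  t_sec <- (seq_len(n) - 1) / sampling_rate
  design <- do.call(cbind, lapply(f_targets, function(f) {
    cbind(cos(2 * pi * f * t_sec), sin(2 * pi * f * t_sec))
  }))
  theta <- qr.solve(design, x)
  a <- theta[seq(1, length(theta), by = 2)]
  b <- theta[seq(2, length(theta), by = 2)]
  complex(real = a, imaginary = -b)
}

# DFT projection oracle at a single frequency (exact for integer
# numbers of cycles per epoch).
dft_amplitude <- function(x, f, sampling_rate) {
  n <- length(x)
  t_sec <- (seq_len(n) - 1) / sampling_rate
  2 * Mod(sum(x * exp(-2i * pi * f * t_sec))) / n
}

# Wrap a bare matrix as an eeg_trial for filter/epoch tests.
matrix_trial <- function(samples, sampling_rate = 2048,
                         stimulus = sweep_stimulus(),
                         channels = NULL) {
  channels <- channels %||% rownames(samples) %||%
    sprintf("ch%d", seq_len(nrow(samples)))
  rownames(samples) <- channels
  structure(
    list(
      samples = samples, channel_names = channels,
      sampling_rate = sampling_rate, stimulus = stimulus,
      meridian = "strong", seed = NULL
    ),
    class = "eeg_trial"
  )
}

silent_noise <- function() {
  noise_config(
    one_over_f_rms = 0, white_rms = 0,
    phase_jitter_sd = 0
  )
}

# Minimal spectra tibble for averaging/SNR tests.
make_spectra <- function(coefficients, frequency = 12, epoch = 0L,
                         channel = "occipital-mean", swept_sf = 2) {
  tibble::tibble(
    epoch = epoch, swept_sf = swept_sf, channel = channel,
    frequency = frequency, coefficient = coefficients,
    amplitude = Mod(coefficients), phase = Arg(coefficients)
  )
}
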