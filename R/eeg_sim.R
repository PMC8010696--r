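#' Sweep stimulus description
#'
#' An 80% contrast, 6 Hz phase-reversing grating whose spatial
#' frequency is swept from 2 to 16 cycles/degree in 10 linear steps
#' over a 10 s trial, repeated ten times — the standard spatial
#' sweep-VEP protocol this package analyses.
#'
#' @param contrast Grating contrast (fraction).
#' @param temporal_freq Phase-reversal rate, Hz. The evoked response of
#'   interest is at its second harmonic (12 Hz by default).
#' @param sweep_start,sweep_end Sweep range, cycles/degree.
#' @param n_steps Number of linear sweep steps (one epoch each).
#' @param duration Trial duration, seconds (must divide evenly into
#'   `n_steps` epochs).
#' @param n_repeats Number of trial repetitions for coherent averaging.
#' @return An object of class `sweep_stimulus`.
#' @export
sweep_stimulus <- function(contrast = 0.80, temporal_freq = 6,
                           sweep_start = 2, sweep_end = 16,
                           n_steps = 10, duration = 10, n_repeats = 10) {
  check_scalar(contrast, "contrast", 0, 1, open_lower = TRUE)
  check_scalar(temporal_freq, "temporal_freq", lower = 0, open_lower = TRUE)
  check_scalar(n_steps, "n_steps", lower = 2)
  check_scalar(duration, "duration", lower = 0, open_lower = TRUE)
  check_scalar(n_repeats, "n_repeats", lower = 1)
  if (sweep_end <= sweep_start) {
    abort("`sweep_end` must exceed `sweep_start`.")
  }
  structure(
    list(
      contrast = contrast, temporal_freq = temporal_freq,
      sweep_start = sweep_start, sweep_end = sweep_end,
      n_steps = as.integer(n_steps), duration = duration,
      n_repeats = as.integer(n_repeats)
    ),
    class = "sweep_stimulus"
  )
}

#' @export
print.sweep_stimulus <- function(x, ...) {
  cat(sprintf(
    "<sweep_stimulus> %g%% contrast, %g Hz reversal, %g-%g cpd in %d steps, %g s x %d repeats\n",
    100 * x$contrast, x$temporal_freq, x$sweep_start, x$sweep_end,
    x$n_steps, x$duration, x$n_repeats
  ))
  invisible(x)
}

#' EEG background-noise configuration
#'
#' Gaussian noise with a 1/f^alpha spectral shape (EEG background is
#' famously 1/f-like) plus broadband white noise, both independent per
#' channel, and a per-trial phase jitter on the evoked response.
#'
#' @param one_over_f_exponent Spectral exponent alpha of the shaped
#'   noise.
#' @param one_over_f_rms RMS of the 1/f-shaped component, microvolts.
#' @param white_rms RMS of the white component, microvolts.
#' @param phase_jitter_sd SD of the per-trial response-phase jitter,
#'   radians.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(one_over_f_exponent = 1, one_over_f_rms = 10,
                         white_rms = 2, phase_jitter_sd = 0.25) {
  check_scalar(one_over_f_exponent, "one_over_f_exponent", lower = 0)
  check_scalar(one_over_f_rms, "one_over_f_rms", lower = 0)
  check_scalar(white_rms, "white_rms", lower = 0)
  check_scalar(phase_jitter_sd, "phase_jitter_sd", lower = 0)
  structure(
    list(
      one_over_f_exponent = one_over_f_exponent,
      one_over_f_rms = one_over_f_rms,
      white_rms = white_rms,
      phase_jitter_sd = phase_jitter_sd
    ),
    class = "noise_config"
  )
}

# 1/f^alpha Gaussian noise of length n, normalized to the requested RMS
# (per realization). Spectral shaping by FFT: white Gaussian noise is
# weighted by f^(-alpha/2) in the frequency domain (DC removed).
one_over_f_noise <- function(n, sampling_rate, exponent, rms) {
  if (rms == 0) {
    return(numeric(n))
  }
  x <- rnorm(n)
  xf <- fft(x)
  freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) *
    sampling_rate / n
  w <- abs(freqs)^(-exponent / 2)
  w[1] <- 0 # kill DC
  y <- Re(fft(xf * w, inverse = TRUE)) / n
  y * rms / sd(y)
}

#' Generate one synthetic sweep-VEP EEG trial
#'
#' Emits an already-digitized multichannel trial. Each of the
#' `n_steps` epochs carries a second-harmonic sinusoid (12 Hz for a
#' 6 Hz reversal rate) whose amplitude declines linearly with the
#' epoch's swept spatial frequency,
#' \deqn{A(f_k) = A_{peak} \, \max\!\left(0,
#'   \frac{f_{thr} - f_k}{f_{thr} - f_{ref}}\right),}
#' reaching zero at the observer's generative sVEP threshold
#' \eqn{f_{thr}} (with \eqn{f_{ref}} the first swept value). The
#' response is present only on the occipital channels Oz, O1 and O2,
#' at the observer's response phase plus a per-trial jitter; all
#' channels receive independent 1/f-shaped plus white Gaussian noise.
#'
#' @param observer An [observer_model()].
#' @param stimulus A [sweep_stimulus()].
#' @param meridian `"strong"` or `"weak"` (selects the generative
#'   threshold).
#' @param noise A [noise_config()].
#' @param channels Channel labels; must contain `"Oz"`, `"O1"`, `"O2"`
#'   exactly once each.
#' @param sampling_rate Sampling rate, Hz.
#' @param seed Optional integer seed; the same seed reproduces the
#'   trial bit-for-bit.
#' @return An object of class `eeg_trial`: `samples` (channels x time
#'   matrix, microvolts), `channel_names`, `sampling_rate`, `stimulus`,
#'   `meridian`, `seed`.
#' @examples
#' trial <- generate_sweep_trial(observer_model(), seed = 1)
#' dim(trial$samples) # 4 channels x 20480 samples
#' @export
generate_sweep_trial <- function(observer, stimulus = sweep_stimulus(),
                                 meridian = c("strong", "weak"),
                                 noise = noise_config(),
                                 channels = c("Oz", "O1", "O2", "Cz"),
                                 sampling_rate = 2048, seed = NULL) {
  stopifnot(
    inherits(observer, "observer_model"),
    inherits(stimulus, "sweep_stimulus"),
    inherits(noise, "noise_config")
  )
  meridian <- match_meridian(meridian)
  required <- c("Oz", "O1", "O2")
  if (!all(tabulate(match(channels, required), 3L) == 1L)) {
    abort("`channels` must contain Oz, O1 and O2 exactly once each.")
  }
  n_total <- round(sampling_rate * stimulus$duration)
  if (n_total %% stimulus$n_steps != 0) {
    abort("trial length must divide evenly into sweep epochs.")
  }
  f2 <- 2 * stimulus$temporal_freq
  sfs <- sweep_frequencies(
    stimulus$sweep_start, stimulus$sweep_end, stimulus$n_steps
  )
  f_thr <- if (meridian == "strong") {
    observer$vep_threshold_strong
  } else {
    observer$vep_threshold_weak
  }
  f_ref <- sfs[1]
  amps <- observer$vep_peak_amplitude *
    pmax(0, (f_thr - sfs) / (f_thr - f_ref))
  epoch_len <- n_total %/% stimulus$n_steps
  t <- (seq_len(n_total) - 1) / sampling_rate
  with_seed(seed, {
    jitter <- if (noise$phase_jitter_sd > 0) {
      rnorm(1, 0, noise$phase_jitter_sd)
    } else {
      0
    }
    amp_t <- rep(amps, each = epoch_len)
    response <- amp_t * cos(2 * pi * f2 * t + observer$response_phase + jitter)
    samples <- matrix(0, nrow = length(channels), ncol = n_total)
    for (ch in seq_along(channels)) {
      noise_ch <- one_over_f_noise(
        n_total, sampling_rate,
        noise$one_over_f_exponent, noise$one_over_f_rms
      )
      if (noise$white_rms > 0) {
        noise_ch <- noise_ch + rnorm(n_total, 0, noise$white_rms)
      }
      samples[ch, ] <- noise_ch
      if (channels[ch] %in% required) {
        samples[ch, ] <- samples[ch, ] + response
      }
    }
    rownames(samples) <- channels
    structure(
      list(
        samples = samples, channel_names = channels,
        sampling_rate = sampling_rate, stimulus = stimulus,
        meridian = meridian, seed = seed
      ),
      class = "eeg_trial"
    )
  })
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf(
    "<eeg_trial> %d channels x %d samples @ %g Hz, %s meridian\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate, x$meridian
  ))
  invisible(x)
}

#' Write / read an EEG trial as a text matrix plus JSON sidecar
#'
#' The samples matrix (channels x time, microvolts) is stored as a
#' plain-text tab-separated file with full double precision; stimulus
#' parameters, channel names, sampling rate, meridian and seed go into
#' a JSON sidecar, so the pair round-trips losslessly.
#'
#' @param trial An `eeg_trial`.
#' @param path_prefix File path without extension; writes
#'   `<prefix>.txt` and `<prefix>.json`.
#' @return `write_eeg_trial()` returns the prefix invisibly;
#'   `read_eeg_trial()` returns the reconstructed `eeg_trial`.
#' @export
write_eeg_trial <- function(trial, path_prefix) {
  stopifnot(inherits(trial, "eeg_trial"))
  txt <- apply(trial$samples, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(txt, paste0(path_prefix, ".txt"))
  sidecar <- list(
    channel_names = trial$channel_names,
    sampling_rate = trial$sampling_rate,
    stimulus = unclass(trial$stimulus),
    sweep_values = sweep_frequencies(
      trial$stimulus$sweep_start, trial$stimulus$sweep_end,
      trial$stimulus$n_steps
    ),
    meridian = trial$meridian,
    seed = trial$seed
  )
  jsonlite::write_json(sidecar, paste0(path_prefix, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path_prefix)
}

#' @rdname write_eeg_trial
#' @export
read_eeg_trial <- function(path_prefix) {
  lines <- readLines(paste0(path_prefix, ".txt"))
  samples <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  sidecar <- jsonlite::read_json(paste0(path_prefix, ".json"),
    simplifyVector = TRUE
  )
  stim <- do.call(sweep_stimulus, sidecar$stimulus[
    c(
      "contrast", "temporal_freq", "sweep_start", "sweep_end",
      "n_steps", "duration", "n_repeats"
    )
  ])
  rownames(samples) <- sidecar$channel_names
  structure(
    list(
      samples = samples, channel_names = sidecar$channel_names,
      sampling_rate = sidecar$sampling_rate, stimulus = stim,
      meridian = sidecar$meridian, seed = sidecar$seed
    ),
    class = "eeg_trial"
  )
}
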