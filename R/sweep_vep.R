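#' Swept spatial frequencies
#'
#' The `n` linear sweep steps from `start` to `end` cycles/degree,
#' inclusive of both ends (step `(end - start) / (n - 1)`). The default
#' protocol sweeps 2 to 16 cpd in 10 steps: 2, 3.6, 5.1, 6.7, 8.2,
#' 9.8, 11.3, 12.9, 14.4, 16 (to 0.1 cpd).
#'
#' @param start,end Sweep range, cycles/degree.
#' @param n Number of steps (>= 2).
#' @return Numeric vector of length `n`.
#' @examples
#' round(sweep_frequencies(), 1)
#' @export
sweep_frequencies <- function(start = 2, end = 16, n = 10) {
  check_scalar(n, "n", lower = 2)
  if (end <= start) abort("`end` must exceed `start`.")
  seq(start, end, length.out = n)
}

#' Zero-phase analysis band-pass filter
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth
#' band-pass, 1-30 Hz by default, to every channel of a trial. The
#' 12 Hz analysis component is preserved to well within 1%.
#'
#' @param trial An `eeg_trial`.
#' @param low,high Band edges, Hz (`high` below Nyquist).
#' @param order Butterworth order.
#' @return The filtered `eeg_trial`.
#' @export
analysis_bandpass <- function(trial, low = 1, high = 30, order = 4) {
  stopifnot(inherits(trial, "eeg_trial"))
  nyq <- trial$sampling_rate / 2
  if (!(low > 0 && high > low && high < nyq)) {
    abort("band edges must satisfy 0 < low < high < Nyquist.")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  trial$samples <- t(apply(trial$samples, 1L, function(x) {
    signal::filtfilt(bf, x)
  }))
  rownames(trial$samples) <- trial$channel_names
  trial
}

#' Split a sweep trial into its per-step epochs
#'
#' Divides the trial into `n_steps` contiguous, non-overlapping
#' segments of equal length; epoch `k` (0-based) is paired with the
#' k-th swept spatial frequency.
#'
#' @param trial An `eeg_trial`.
#' @return A tibble with columns `epoch` (0-based index), `swept_sf`
#'   (cycles/degree) and `data` (list of channels x samples matrices).
#' @export
epoch_trial <- function(trial) {
  stopifnot(inherits(trial, "eeg_trial"))
  n_steps <- trial$stimulus$n_steps
  n_total <- ncol(trial$samples)
  if (n_total != round(trial$sampling_rate * trial$stimulus$duration) ||
    n_total %% n_steps != 0) {
    abort("trial length does not divide into equal sweep epochs.")
  }
  epoch_len <- n_total %/% n_steps
  sfs <- sweep_frequencies(
    trial$stimulus$sweep_start, trial$stimulus$sweep_end, n_steps
  )
  segs <- lapply(seq_len(n_steps), function(k) {
    trial$samples[, ((k - 1) * epoch_len + 1):(k * epoch_len), drop = FALSE]
  })
  tibble(epoch = seq_len(n_steps) - 1L, swept_sf = sfs, data = segs)
}

#' Recursive-least-squares harmonic coefficients of one epoch
#'
#' Recursively fits
#' \deqn{y(t) \approx \sum_j a_j \cos(2\pi f_j t) + b_j \sin(2\pi f_j t)}
#' with exponential forgetting and reads the fit out at the epoch end;
#' the complex coefficient \eqn{a_j - i b_j} carries the amplitude
#' (modulus) and phase (argument) of the component at `f_j`. With
#' `forgetting_factor = 1` the result equals the ordinary
#' least-squares projection on the epoch (and, for an integer number
#' of cycles, the DFT bin value).
#'
#' @param x A numeric vector (one channel) or a channels x samples
#'   matrix with row names.
#' @param f_targets Frequencies to estimate, Hz (distinct, below
#'   Nyquist). Default: the 12 Hz second harmonic and its 11/13 Hz
#'   noise neighbours.
#' @param sampling_rate Sampling rate, Hz.
#' @param forgetting_factor RLS memory constant in `(0.9, 1]`.
#' @param init_gain Initial inverse-covariance scale of the recursion
#'   (larger values weaken the implicit regularisation but amplify
#'   round-off; the default keeps both below about 1e-8 relative).
#' @return A tibble with columns `channel`, `frequency`, `coefficient`
#'   (complex), `amplitude` (microvolts) and `phase` (radians).
#' @examples
#' fs <- 256
#' t <- (0:(fs - 1)) / fs
#' rls_coefficients(3 * cos(2 * pi * 12 * t),
#'   f_targets = 12,
#'   sampling_rate = fs, forgetting_factor = 1
#' )
#' @export
rls_coefficients <- function(x, f_targets = c(11, 12, 13),
                             sampling_rate = 2048,
                             forgetting_factor = 0.9995,
                             init_gain = 1e6) {
  if (anyDuplicated(f_targets)) {
    abort("`f_targets` must be distinct frequencies.")
  }
  if (any(f_targets >= sampling_rate / 2)) {
    abort("`f_targets` must lie below the Nyquist frequency.")
  }
  if (!(forgetting_factor > 0.9 && forgetting_factor <= 1)) {
    abort("`forgetting_factor` must lie in (0.9, 1].")
  }
  y <- if (is.matrix(x)) t(x) else matrix(x, ncol = 1)
  channels <- if (is.matrix(x)) {
    rownames(x) %||% sprintf("ch%d", seq_len(nrow(x)))
  } else {
    "ch1"
  }
  n <- nrow(y)
  t_sec <- (seq_len(n) - 1) / sampling_rate
  design <- do.call(cbind, lapply(f_targets, function(f) {
    cbind(cos(2 * pi * f * t_sec), sin(2 * pi * f * t_sec))
  }))
  theta <- rls_fit_cpp(design, y, forgetting_factor, init_gain)
  out <- lapply(seq_along(channels), function(ci) {
    a <- theta[seq(1, 2 * length(f_targets), by = 2), ci]
    b <- theta[seq(2, 2 * length(f_targets), by = 2), ci]
    coefficient <- complex(real = a, imaginary = -b)
    tibble(
      channel = channels[ci],
      frequency = f_targets,
      coefficient = coefficient,
      amplitude = Mod(coefficient),
      phase = Arg(coefficient)
    )
  })
  purrr::list_rbind(out)
}

#' Average harmonic coefficients over the occipital electrodes
#'
#' Complex (amplitude-and-phase preserving) mean of the Oz, O1 and O2
#' coefficients, per epoch and frequency.
#'
#' @param spectra A tibble of coefficients with a `channel` column (as
#'   produced by [rls_coefficients()], possibly carrying extra grouping
#'   columns such as `epoch`).
#' @param channels The channels to average (all must be present).
#' @return The same tibble structure with a single
#'   `"occipital-mean"` channel.
#' @export
occipital_average <- function(spectra, channels = c("Oz", "O1", "O2")) {
  stopifnot(is.data.frame(spectra), "channel" %in% names(spectra))
  if (!all(channels %in% spectra$channel)) {
    abort(sprintf(
      "missing channel(s): %s",
      paste(setdiff(channels, unique(spectra$channel)), collapse = ", ")
    ))
  }
  keep <- spectra$channel %in% channels
  x <- spectra[keep, ]
  group_cols <- setdiff(
    names(x), c("channel", "coefficient", "amplitude", "phase")
  )
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      coefficient = mean(.data$coefficient), .groups = "drop"
    ) |>
    dplyr::mutate(
      channel = "occipital-mean",
      amplitude = Mod(.data$coefficient),
      phase = Arg(.data$coefficient)
    )
  dplyr::relocate(out, "channel")
}

#' Harmonic spectra of every epoch of a sweep trial
#'
#' Convenience chain for one trial: zero-phase band-pass filter,
#' epoching, RLS coefficient extraction per channel, and occipital
#' averaging.
#'
#' @param trial An `eeg_trial`.
#' @param f_targets Frequencies to estimate, Hz; defaults to the
#'   second harmonic of the stimulus reversal rate plus the adjacent
#'   11/13 Hz noise bins.
#' @param forgetting_factor RLS memory constant.
#' @param bandpass Band edges in Hz, or `NULL` to skip filtering.
#' @param average_occipital Average Oz/O1/O2 into one virtual channel
#'   (default) or keep per-channel coefficients.
#' @return A tibble: `epoch`, `swept_sf`, `channel`, `frequency`,
#'   `coefficient`, `amplitude`, `phase`.
#' @export
analyze_sweep_trial <- function(trial, f_targets = NULL,
                                forgetting_factor = 0.9995,
                                bandpass = c(1, 30),
                                average_occipital = TRUE) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (is.null(f_targets)) {
    f2 <- 2 * trial$stimulus$temporal_freq
    f_targets <- c(f2 - 1, f2, f2 + 1)
  }
  if (!is.null(bandpass)) {
    trial <- analysis_bandpass(trial, bandpass[1], bandpass[2])
  }
  epochs <- epoch_trial(trial)
  spectra <- purrr::pmap(epochs, function(epoch, swept_sf, data) {
    dplyr::mutate(
      rls_coefficients(data, f_targets, trial$sampling_rate,
        forgetting_factor),
      epoch = epoch, swept_sf = swept_sf
    )
  })
  spectra <- purrr::list_rbind(spectra)
  spectra <- dplyr::relocate(spectra, "epoch", "swept_sf")
  if (average_occipital) occipital_average(spectra) else spectra
}

#' Coherently (vector) average spectra across trials
#'
#' Averages the complex per-epoch coefficients across repeated trials,
#' so phase-consistent signal adds while random-phase noise cancels.
#' The vector standard error of the vector mean pools the sampling
#' variances of the real and imaginary parts:
#' \eqn{SE = \sqrt{\mathrm{var}(\Re)/N + \mathrm{var}(\Im)/N}}.
#'
#' @param trial_spectra A list of per-trial spectra tibbles (from
#'   [analyze_sweep_trial()]), or one tibble with a `trial` column.
#'   At least two trials with identical epoch/frequency structure.
#' @return A tibble: `epoch`, `swept_sf`, `channel`, `frequency`,
#'   `coefficient` (vector mean), `amplitude` (modulus of the vector
#'   mean), `phase`, `vector_se`, `n_trials`.
#' @export
coherent_average <- function(trial_spectra) {
  if (is.data.frame(trial_spectra)) {
    if (!"trial" %in% names(trial_spectra)) {
      abort("a single spectra tibble needs a `trial` column.")
    }
    combined <- as_tibble(trial_spectra)
  } else {
    combined <- purrr::list_rbind(
      purrr::map2(trial_spectra, seq_along(trial_spectra), function(s, i) {
        dplyr::mutate(as_tibble(s), trial = i)
      })
    )
  }
  if (length(unique(combined$trial)) < 2L) {
    abort("coherent averaging needs at least two trials.")
  }
  counts <- combined |>
    dplyr::count(.data$epoch, .data$swept_sf, .data$channel, .data$frequency)
  if (length(unique(counts$n)) != 1L) {
    abort("trials have mismatched epoch/frequency structure.")
  }
  combined |>
    dplyr::group_by(
      .data$epoch, .data$swept_sf, .data$channel, .data$frequency
    ) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      vector_se = sqrt(
        var(Re(.data$coefficient)) / dplyr::n() +
          var(Im(.data$coefficient)) / dplyr::n()
      ),
      coefficient = mean(.data$coefficient),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      amplitude = Mod(.data$coefficient),
      phase = Arg(.data$coefficient)
    ) |>
    dplyr::relocate(
      "epoch", "swept_sf", "channel", "frequency",
      "coefficient", "amplitude", "phase", "vector_se", "n_trials"
    )
}

#' Per-epoch signal-to-noise ratio of the sweep response
#'
#' Noise is the mean modulus of the vector-averaged coefficients at
#' the adjacent noise frequencies (11 and 13 Hz for a 12 Hz signal);
#' SNR is the signal amplitude divided by that noise amplitude. A
#' noiseless epoch with signal reports `Inf`; an epoch with neither
#' signal nor noise reports 0.
#'
#' @param spectra Vector-averaged spectra from [coherent_average()] (or
#'   a single trial's spectra from [analyze_sweep_trial()]).
#' @param signal_freq Signal frequency, Hz.
#' @param noise_freqs Adjacent noise frequencies, Hz.
#' @return An object of class `sweep_response`: a tibble with one row
#'   per epoch — `epoch`, `swept_sf`, `amplitude`, `phase`,
#'   `vector_se` (if present), `noise_amplitude`, `snr`, `n_trials`.
#' @export
noise_and_snr <- function(spectra, signal_freq = 12,
                          noise_freqs = c(11, 13)) {
  stopifnot(is.data.frame(spectra))
  if (!all(c(signal_freq, noise_freqs) %in% spectra$frequency)) {
    abort("spectra must contain the signal and noise frequencies.")
  }
  sig <- spectra[spectra$frequency == signal_freq, ]
  noi <- spectra[spectra$frequency %in% noise_freqs, ] |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(
      noise_amplitude = mean(Mod(.data$coefficient)), .groups = "drop"
    )
  out <- dplyr::left_join(sig, noi, by = "epoch") |>
    dplyr::mutate(
      snr = dplyr::case_when(
        .data$noise_amplitude > 0 ~ .data$amplitude / .data$noise_amplitude,
        .data$amplitude > 0 ~ Inf,
        TRUE ~ 0
      )
    ) |>
    dplyr::arrange(.data$epoch)
  keep <- intersect(
    c(
      "epoch", "swept_sf", "channel", "amplitude", "phase",
      "vector_se", "noise_amplitude", "snr", "n_trials"
    ),
    names(out)
  )
  out <- out[, keep]
  class(out) <- c("sweep_response", class(out))
  attr(out, "signal_freq") <- signal_freq
  attr(out, "noise_freqs") <- noise_freqs
  out
}

#' Sweep-VEP spatial-frequency threshold by regression to zero
#'
#' Scores the sweep response function and extrapolates the response
#' amplitude to zero. The scoring window runs from the
#' highest-amplitude epoch whose SNR exceeds the criterion (3:1 by
#' default) through the last subsequent epoch still exceeding it; an
#' ordinary least-squares line of amplitude against swept spatial
#' frequency over the window is extended to zero amplitude, and the
#' crossing is the threshold (extrapolation beyond the last swept
#' frequency is permitted). Fits with fewer than `min_epochs` window
#' epochs or a non-negative slope are flagged invalid rather than
#' dropped.
#'
#' @param response A `sweep_response` from [noise_and_snr()].
#' @param criterion_snr SNR validity criterion (signal must exceed
#'   `criterion_snr` times the adjacent-bin noise).
#' @param min_epochs Minimum number of window epochs for a valid fit.
#' @return An object of class `vep_fit`: `threshold` (cycles/degree),
#'   `slope` (microvolts per cpd), `intercept` (microvolts),
#'   `included_epochs` (0-based indices), `valid`, `reason`. Use
#'   [glance()] for a one-row tibble.
#' @export
estimate_svep_threshold <- function(response, criterion_snr = 3,
                                    min_epochs = 3) {
  stopifnot(is.data.frame(response))
  need <- c("epoch", "swept_sf", "amplitude", "snr")
  if (!all(need %in% names(response))) {
    abort("`response` needs columns epoch, swept_sf, amplitude, snr.")
  }
  resp <- dplyr::arrange(as_tibble(response), .data$epoch)
  pass <- which(resp$snr > criterion_snr)
  fit <- list(
    threshold = NA_real_, slope = NA_real_, intercept = NA_real_,
    included_epochs = integer(0), criterion_snr = criterion_snr,
    valid = FALSE, reason = NA_character_, response = resp
  )
  if (length(pass) == 0L) {
    fit$reason <- "no-signal-window"
    return(structure(fit, class = "vep_fit"))
  }
  start <- pass[which.max(resp$amplitude[pass])]
  end <- max(pass[pass >= start])
  window <- seq.int(start, end)
  fit$included_epochs <- resp$epoch[window]
  if (length(window) < min_epochs) {
    fit$reason <- "too-few-epochs"
    return(structure(fit, class = "vep_fit"))
  }
  ols <- lm(amplitude ~ swept_sf, data = resp[window, ])
  slope <- coef(ols)[["swept_sf"]]
  intercept <- coef(ols)[["(Intercept)"]]
  fit$slope <- slope
  fit$intercept <- intercept
  if (slope >= 0) {
    fit$reason <- "non-negative-slope"
    return(structure(fit, class = "vep_fit"))
  }
  fit$threshold <- -intercept / slope
  fit$valid <- TRUE
  structure(fit, class = "vep_fit")
}

#' @export
print.vep_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "<vep_fit> threshold %.2f cpd (slope %.3f uV/cpd, %d window epochs)\n",
      x$threshold, x$slope, length(x$included_epochs)
    ))
  } else {
    cat(sprintf("<vep_fit> invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' Full sweep-VEP analysis of repeated trials
#'
#' Chains [analyze_sweep_trial()] over the repeated trials,
#' [coherent_average()], [noise_and_snr()] and
#' [estimate_svep_threshold()].
#'
#' @param trials List of `eeg_trial` objects (the repeated sweeps).
#' @param criterion_snr SNR validity criterion.
#' @param noise_offsets Noise-bin offsets from the signal frequency,
#'   Hz.
#' @param forgetting_factor RLS memory constant.
#' @param bandpass Analysis band, Hz.
#' @return A list with elements `response` (the `sweep_response`
#'   tibble) and `fit` (the `vep_fit`).
#' @export
analyze_sweep_trials <- function(trials, criterion_snr = 3,
                                 noise_offsets = c(-1, 1),
                                 forgetting_factor = 0.9995,
                                 bandpass = c(1, 30)) {
  stopifnot(length(trials) >= 2L)
  f2 <- 2 * trials[[1]]$stimulus$temporal_freq
  f_targets <- c(f2, f2 + noise_offsets)
  spectra <- purrr::map(trials, analyze_sweep_trial,
    f_targets = f_targets, forgetting_factor = forgetting_factor,
    bandpass = bandpass
  )
  avg <- coherent_average(spectra)
  response <- noise_and_snr(avg,
    signal_freq = f2, noise_freqs = f2 + noise_offsets
  )
  list(
    response = response,
    fit = estimate_svep_threshold(response, criterion_snr = criterion_snr)
  )
}
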