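test_that("the sweep grid spans 2-16 cpd in 10 linear steps", {
  sfs <- sweep_frequencies(2, 16, 10)
  expect_length(sfs, 10)
  expect_equal(sfs[1], 2)
  expect_equal(sfs[10], 16)
  expect_equal(diff(sfs), rep(14 / 9, 9), tolerance = 1e-12)
  expect_error(sweep_frequencies(2, 16, 1), "lie in")
  expect_error(sweep_frequencies(16, 2, 10), "exceed")
})

test_that("the analysis band-pass preserves 12 Hz and rejects 50 Hz and DC", {
  fs <- 2048
  t_sec <- (0:(fs * 4 - 1)) / fs
  mk <- function(x) matrix_trial(matrix(x, nrow = 1), sampling_rate = fs)
  f12 <- analysis_bandpass(mk(sin(2 * pi * 12 * t_sec)))
  expect_equal(
    dft_amplitude(f12$samples[1, ], 12, fs), 1,
    tolerance = 0.01
  )
  f50 <- analysis_bandpass(mk(sin(2 * pi * 50 * t_sec)))
  expect_lt(
    20 * log10(dft_amplitude(f50$samples[1, ], 50, fs)), -20
  )
  fdc <- analysis_bandpass(mk(rep(1, fs * 4)))
  expect_lt(mean(abs(fdc$samples[1, fs:(3 * fs)])), 0.01)
  expect_error(analysis_bandpass(mk(rep(1, fs * 4)), low = 30, high = 1), "band")
})

test_that("epoching partitions the trial against the sweep grid", {
  trial <- generate_sweep_trial(observer_model(), seed = 6)
  epochs <- epoch_trial(trial)
  expect_equal(nrow(epochs), 10L)
  expect_equal(epochs$epoch, 0:9)
  expect_equal(epochs$swept_sf, sweep_frequencies())
  expect_true(all(vapply(epochs$data, ncol, integer(1)) == 2048L))
  # concatenating the epochs reconstructs the trial exactly
  expect_identical(do.call(cbind, epochs$data), trial$samples)
  bad <- trial
  bad$samples <- bad$samples[, 1:20000]
  expect_error(epoch_trial(bad), "divide")
})

test_that("RLS with unit forgetting matches the least-squares/DFT oracle", {
  fs <- 2048
  t_sec <- (0:(fs - 1)) / fs
  x <- 3 * cos(2 * pi * 12 * t_sec + 1.1) + 0.8 * sin(2 * pi * 7 * t_sec)
  got <- rls_coefficients(x,
    f_targets = c(11, 12, 13), sampling_rate = fs,
    forgetting_factor = 1
  )
  c12 <- got$coefficient[got$frequency == 12]
  expect_equal(Mod(c12), 3, tolerance = 1e-6)
  expect_equal(Arg(c12), 1.1, tolerance = 1e-6)
  expect_equal(Mod(c12), dft_amplitude(x, 12, fs), tolerance = 1e-6)
  # no 12 Hz content: coefficient at numerical zero
  y <- sin(2 * pi * 9 * t_sec)
  g0 <- rls_coefficients(y, c(11, 12, 13), fs, forgetting_factor = 1)
  expect_lt(max(g0$amplitude), 1e-6)
})

test_that("RLS equals the OLS projection on random epochs", {
  fs <- 512
  t_sec <- (0:(fs - 1)) / fs
  set.seed(41)
  for (i in 1:25) {
    amp <- runif(1, 0.5, 5)
    phi <- runif(1, -pi, pi)
    x <- amp * cos(2 * pi * 12 * t_sec + phi) + rnorm(fs, 0, 1)
    oracle <- ols_coefficients(x, c(11, 12, 13), fs)
    got <- rls_coefficients(x, c(11, 12, 13), fs, forgetting_factor = 1)
    expect_equal(got$coefficient, oracle, tolerance = 1e-6)
  }
})

test_that("RLS amplitude is phase-equivariant", {
  fs <- 1024
  t_sec <- (0:(fs - 1)) / fs
  shift <- 0.8
  a <- rls_coefficients(
    2 * cos(2 * pi * 12 * t_sec), 12, fs,
    forgetting_factor = 1
  )
  b <- rls_coefficients(
    2 * cos(2 * pi * 12 * t_sec + shift), 12, fs,
    forgetting_factor = 1
  )
  expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
  expect_equal(b$phase - a$phase, shift, tolerance = 1e-9)
  expect_error(rls_coefficients(1:10, c(12, 12), fs), "distinct")
  expect_error(rls_coefficients(1:10, 600, 1024), "Nyquist")
})

test_that("occipital averaging is the complex mean of Oz, O1, O2", {
  mk <- function(oz, o1, o2) {
    tibble::tibble(
      epoch = 0L, swept_sf = 2,
      channel = c("Oz", "O1", "O2"),
      frequency = 12,
      coefficient = c(oz, o1, o2),
      amplitude = Mod(c(oz, o1, o2)),
      phase = Arg(c(oz, o1, o2))
    )
  }
  # identical channels pass through unchanged
  same <- occipital_average(mk(2 + 1i, 2 + 1i, 2 + 1i))
  expect_equal(same$coefficient, 2 + 1i)
  expect_equal(same$channel, "occipital-mean")
  # opposite phases cancel
  expect_equal(
    occipital_average(mk(1 + 0i, -1 + 0i, 0 + 0i))$amplitude, 0
  )
  # worked complex mean
  expect_equal(
    occipital_average(mk(1 + 0i, 0 + 1i, 0 + 0i))$coefficient,
    (1 + 1i) / 3
  )
  expect_error(occipital_average(mk(1, 1, 1)[1:2, ]), "missing channel")
})

test_that("coherent averaging adds phase-locked signal and cancels noise", {
  base <- make_spectra(2 * exp(1i * 0.5))
  # identical trials: amplitude preserved, vector SE zero
  avg <- coherent_average(list(base, base, base))
  expect_equal(avg$amplitude, 2)
  expect_equal(avg$vector_se, 0)
  expect_equal(avg$n_trials, 3L)
  # random phases, fixed modulus: vector mean shrinks toward zero
  set.seed(51)
  shrink <- vapply(c(10, 1000), function(n) {
    coherent_average(
      lapply(seq_len(n), function(i) {
        make_spectra(exp(1i * runif(1, -pi, pi)))
      })
    )$amplitude
  }, numeric(1))
  expect_lt(shrink[2], shrink[1])
  expect_lt(shrink[2], 0.1)
  expect_error(coherent_average(list(base)), "at least two")
  expect_error(
    coherent_average(list(base, make_spectra(c(1 + 0i, 1 + 0i),
      frequency = c(11, 12), epoch = c(0L, 0L)
    ))),
    "mismatched"
  )
})

test_that("SNR divides signal amplitude by the adjacent-bin noise mean", {
  sp <- tibble::tibble(
    epoch = 0L, swept_sf = 2, channel = "occipital-mean",
    frequency = c(11, 12, 13),
    coefficient = c(1 + 0i, 6 + 0i, 3 + 0i),
    amplitude = c(1, 6, 3), phase = 0
  )
  r <- noise_and_snr(sp)
  expect_equal(r$noise_amplitude, 2)
  expect_equal(r$snr, 3)
  # noiseless signal: infinite SNR sentinel
  sp$coefficient <- c(0 + 0i, 6 + 0i, 0 + 0i)
  sp$amplitude <- c(0, 6, 0)
  expect_equal(noise_and_snr(sp)$snr, Inf)
  # neither signal nor noise: SNR zero
  sp$coefficient <- c(0 + 0i, 0 + 0i, 0 + 0i)
  sp$amplitude <- c(0, 0, 0)
  expect_equal(noise_and_snr(sp)$snr, 0)
  expect_error(noise_and_snr(sp[1:2, ]), "frequencies")
})

test_that("pure-noise epochs have SNR distributed around one", {
  fs <- 512
  set.seed(61)
  snrs <- replicate(60, {
    x <- rnorm(fs)
    sp <- rls_coefficients(x, c(11, 12, 13), fs, forgetting_factor = 1)
    sp$epoch <- 0L
    sp$swept_sf <- 2
    noise_and_snr(sp)$snr
  })
  expect_gt(median(snrs), 0.4)
  expect_lt(median(snrs), 2.5)
})

mk_response <- function(amplitude, snr,
                        sfs = sweep_frequencies()) {
  structure(
    tibble::tibble(
      epoch = seq_along(sfs) - 1L, swept_sf = sfs,
      amplitude = amplitude, phase = 0, noise_amplitude = 1,
      snr = snr
    ),
    class = c("sweep_response", "tbl_df", "tbl", "data.frame")
  )
}

test_that("regression threshold recovers a linear ramp exactly", {
  sfs <- sweep_frequencies()
  # zero crossing at 14.5 cpd, all epochs above criterion
  amps <- pmax(0, 14.5 - sfs) * 0.4
  fit <- estimate_svep_threshold(mk_response(amps, ifelse(amps > 0, 10, 0)))
  expect_true(fit$valid)
  expect_equal(fit$threshold, 14.5, tolerance = 1e-9)
  expect_lt(fit$slope, 0)
  # crossing beyond the sweep end extrapolates to 19 cpd
  amps19 <- (19 - sfs) * 0.3
  fit19 <- estimate_svep_threshold(mk_response(amps19, rep(10, 10)))
  expect_true(fit19$valid)
  expect_equal(fit19$threshold, 19, tolerance = 1e-9)
})

test_that("threshold fits are flagged rather than dropped when invalid", {
  sfs <- sweep_frequencies()
  none <- estimate_svep_threshold(mk_response(rep(1, 10), rep(1, 10)))
  expect_false(none$valid)
  expect_equal(none$reason, "no-signal-window")
  few <- estimate_svep_threshold(
    mk_response(rep(1, 10), c(10, 10, rep(0, 8)))
  )
  expect_false(few$valid)
  expect_equal(few$reason, "too-few-epochs")
  # flat profile: full window but zero slope, no crossing definable
  rising <- estimate_svep_threshold(mk_response(rep(3, 10), rep(10, 10)))
  expect_false(rising$valid)
  expect_equal(rising$reason, "non-negative-slope")
  gl <- glance(rising)
  expect_false(gl$valid)
  expect_equal(gl$reason, "non-negative-slope")
})

test_that("the scoring window starts at the passing amplitude peak", {
  sfs <- sweep_frequencies()
  amps <- c(1, 4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5, 0.2)
  snr <- c(0.5, rep(10, 7), 2, 2)
  fit <- estimate_svep_threshold(mk_response(amps, snr))
  expect_equal(fit$included_epochs, 1:7)
  expect_true(fit$valid)
})

test_that("coherent gain of phase-locked signal over noise grows as sqrt(N)", {
  set.seed(71)
  snr_for_n <- function(n) {
    trials <- lapply(seq_len(n), function(i) {
      sig <- make_spectra(3 + 0i, frequency = 12)
      noi1 <- make_spectra(
        complex(real = rnorm(1), imaginary = rnorm(1)),
        frequency = 11
      )
      noi2 <- make_spectra(
        complex(real = rnorm(1), imaginary = rnorm(1)),
        frequency = 13
      )
      dplyr::bind_rows(sig, noi1, noi2)
    })
    noise_and_snr(coherent_average(trials))$snr
  }
  reps <- 40
  s4 <- median(replicate(reps, snr_for_n(4)))
  s36 <- median(replicate(reps, snr_for_n(36)))
  # 9x the trials: expect about 3x the SNR
  expect_gt(s36 / s4, 1.8)
  expect_lt(s36 / s4, 5)
})
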