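test_that("log-parabola CSF evaluates to its defining formula", {
  csf <- true_csf(
    peak_gain = 100, peak_sf = 2, log_bandwidth = 2,
    low_freq_truncation = 0
  )
  # peak identity
  expect_equal(csf_sensitivity(csf, 2), 100)
  # hand evaluation at 8 cpd: log10 S = 2 - 4*log10(2)*(log10(4)/2)^2
  expected <- 10^(2 - 4 * log10(2) * (log10(8 / 2) / 2)^2)
  expect_equal(csf_sensitivity(csf, 8), expected, tolerance = 1e-12)
  # symmetric in log f about the peak
  expect_equal(csf_sensitivity(csf, 1), csf_sensitivity(csf, 4))
})

test_that("low-frequency truncation floors the parabola on the low side only", {
  csf <- true_csf(
    peak_gain = 100, peak_sf = 4, log_bandwidth = 1,
    low_freq_truncation = 0.5
  )
  # far below the peak the parabola is tiny but the floor holds at 50
  expect_equal(csf_sensitivity(csf, 0.1), 50)
  # the high side is never floored
  expect_lt(csf_sensitivity(csf, 40), 50)
  expect_error(csf_sensitivity(csf, -1), "positive")
})

test_that("meridians with identical CSFs are interchangeable", {
  csf <- true_csf()
  obs <- observer_model(csf_strong = csf, csf_weak = csf)
  for (f in c(0.5, 2, 8, 16)) {
    expect_equal(
      true_sensitivity(obs, f, "strong"),
      true_sensitivity(obs, f, "weak")
    )
  }
})

test_that("weak meridian may never exceed the strong meridian", {
  expect_error(
    observer_model(
      csf_strong = true_csf(peak_gain = 50),
      csf_weak = true_csf(peak_gain = 60)
    ),
    "weak-meridian"
  )
})

test_that("2IFC psychometric function has guessing floor and ceiling", {
  obs <- observer_model(lapse_rate = 0)
  # contrast -> 0: performance collapses to the 50% guess rate
  expect_equal(p_correct_2ifc(obs, 4, 1e-9, "strong"), 0.5,
    tolerance = 1e-6
  )
  # high-contrast grating far above threshold: certainty
  expect_equal(p_correct_2ifc(obs, 4, 1, "strong"), 1, tolerance = 1e-6)
  expect_error(p_correct_2ifc(obs, 4, 0, "strong"), "contrast")
  expect_error(p_correct_2ifc(obs, 4, 1.2, "strong"), "contrast")
})

test_that("Monte-Carlo frequency matches the closed-form Weibull mid-level", {
  obs <- observer_model()
  alpha <- 1 / true_sensitivity(obs, 4, "strong")
  p_mid <- obs$guess_rate +
    (1 - obs$guess_rate - obs$lapse_rate) * (1 - exp(-1))
  set.seed(11)
  hits <- simulate_2ifc_trial(obs, 4, rep(alpha, 1e5), "strong")
  expect_equal(mean(hits), p_mid, tolerance = 0.01)
})

test_that("detection probability is non-decreasing in contrast", {
  obs <- observer_model()
  alpha <- 1 / true_sensitivity(obs, 8, "strong")
  contrasts <- alpha * c(0.5, 1, 2)
  set.seed(21)
  rates <- vapply(contrasts, function(cc) {
    mean(simulate_2ifc_trial(obs, 8, rep(cc, 1e4), "strong"))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("threshold_at_level inverts the psychometric function", {
  obs <- observer_model()
  c793 <- threshold_at_level(obs, 4, "strong", level = 0.793)
  expect_equal(p_correct_2ifc(obs, 4, c793, "strong"), 0.793,
    tolerance = 1e-12
  )
})

test_that("cohorts reproduce the emulated group sizes and are seeded", {
  cohort <- generate_cohort(seed = 4)
  counts <- dplyr::count(cohort, group)
  expect_equal(counts$n[counts$group == "AST"], 20L)
  expect_equal(counts$n[counts$group == "MA"], 19L)
  again <- generate_cohort(seed = 4)
  expect_identical(cohort$gain_drop, again$gain_drop)
  expect_identical(
    cohort$observer[[5]]$csf_strong,
    again$observer[[5]]$csf_strong
  )
  # MA configured with the larger mean generative disparity
  expect_gt(
    mean(cohort$gain_drop[cohort$group == "MA"]),
    mean(cohort$gain_drop[cohort$group == "AST"])
  )
})

test_that("zero-spread cohort specs produce identical observers", {
  spec <- cohort_spec(groups = tibble::tibble(
    group = "G", n_eyes = 3,
    log_gain_mean = 1.6, log_gain_sd = 0,
    peak_sf_mean = 3, log_peak_sf_sd = 0,
    bandwidth_mean = 0.9, bandwidth_sd = 0,
    gain_drop_mean = 0.2, gain_drop_sd = 0,
    bw_ratio_mean = 0.9, bw_ratio_sd = 0,
    vep_threshold_mean = 18, vep_threshold_sd = 0,
    vep_disparity_mean = 2, vep_disparity_sd = 0
  ))
  cohort <- generate_cohort(spec, seed = 1)
  expect_identical(cohort$observer[[1]], cohort$observer[[3]])
  expect_error(
    cohort_spec(groups = tibble::tibble(
      group = "G", n_eyes = 0,
      log_gain_mean = 1.6, log_gain_sd = 0,
      peak_sf_mean = 3, log_peak_sf_sd = 0,
      bandwidth_mean = 0.9, bandwidth_sd = 0,
      gain_drop_mean = 0.2, gain_drop_sd = 0,
      bw_ratio_mean = 0.9, bw_ratio_sd = 0,
      vep_threshold_mean = 18, vep_threshold_sd = 0,
      vep_disparity_mean = 2, vep_disparity_sd = 0
    )),
    "positive"
  )
})
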