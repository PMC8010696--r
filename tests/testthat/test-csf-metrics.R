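test_that("thresholds convert to reciprocal log sensitivities", {
  pts <- thresholds_to_csf(data.frame(sf = 4, threshold = 0.01))
  expect_equal(pts$log10_sf, log10(4))
  expect_equal(pts$log10_sensitivity, 2)
  # threshold 1 (100% contrast) maps to log sensitivity 0
  pts1 <- thresholds_to_csf(data.frame(sf = 8, threshold = 1))
  expect_equal(pts1$log10_sensitivity, 0)
  # the 7-SF grid yields 7 points; non-converged cells are dropped
  grid <- data.frame(
    sf = c(0.5, 1, 2, 4, 8, 12, 16),
    threshold = c(0.05, 0.03, 0.02, 0.02, 0.04, 0.08, 0.15)
  )
  expect_equal(nrow(thresholds_to_csf(grid)), 7L)
  grid$converged <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  dropped <- thresholds_to_csf(grid)
  expect_equal(nrow(dropped), 6L)
  expect_equal(attr(dropped, "n_dropped"), 1L)
  expect_error(thresholds_to_csf(data.frame(sf = 1, threshold = 1.5)), "0, 1")
  expect_error(thresholds_to_csf(grid[0, ]), "non-empty")
})

test_that("AULCSF of a flat log CSF is height times band width", {
  pts <- thresholds_to_csf(data.frame(
    sf = c(1, 4, 16), threshold = rep(0.1, 3)
  ))
  expect_equal(compute_aulcsf(pts), log10(18 / 1.5), tolerance = 1e-12)
  # sensitivity <= 1 everywhere: floored to zero area
  flat0 <- thresholds_to_csf(data.frame(
    sf = c(1, 4, 16), threshold = rep(1, 3)
  ))
  expect_equal(compute_aulcsf(flat0), 0)
  expect_error(compute_aulcsf(pts[1:2, ]), "at least 3")
})

test_that("AULCSF is stable under grid refinement", {
  shape <- function(sf) 1.65 - 1.204 * ((log10(sf / 3)) / 0.9)^2
  coarse_sf <- c(0.5, 1, 2, 4, 8, 12, 16)
  fine_sf <- 10^seq(log10(0.5), log10(16), length.out = 70)
  mk <- function(sfs) {
    tibble::tibble(
      sf = sfs, log10_sf = log10(sfs),
      log10_sensitivity = shape(sfs)
    )
  }
  a_coarse <- compute_aulcsf(mk(coarse_sf))
  a_fine <- compute_aulcsf(mk(fine_sf))
  expect_equal(a_coarse, a_fine, tolerance = 0.05)
})

test_that("AULCSF is shift-equivariant away from the floor", {
  base_sf <- c(1, 2, 4, 8, 16)
  ys <- c(0.8, 1.2, 1.3, 1.0, 0.6)
  mk <- function(shift) {
    tibble::tibble(
      sf = base_sf, log10_sf = log10(base_sf),
      log10_sensitivity = ys + shift
    )
  }
  k <- 0.4
  expect_equal(
    compute_aulcsf(mk(k)) - compute_aulcsf(mk(0)),
    k * log10(18 / 1.5),
    tolerance = 1e-10
  )
})

test_that("CSF acuity interpolates the zero crossing of the falling limb", {
  pts <- tibble::tibble(
    sf = c(8, 16), log10_sf = log10(c(8, 16)),
    log10_sensitivity = c(0.3, -0.3)
  )
  acu <- compute_csf_acuity(pts)
  expect_equal(as.numeric(acu), (log10(8) + log10(16)) / 2, tolerance = 1e-12)
  expect_false(attr(acu, "extrapolated"))
})

test_that("acuity extrapolates (and flags) when all sensitivities exceed 1", {
  # descending limb ending at +0.859 at 16 cpd forces extrapolation
  pts <- tibble::tibble(
    sf = c(8, 12, 16), log10_sf = log10(c(8, 12, 16)),
    log10_sensitivity = c(1.446, 1.245, 0.859)
  )
  acu <- compute_csf_acuity(pts)
  expect_true(attr(acu, "extrapolated"))
  expect_gt(as.numeric(acu), log10(16))
  # no crossing is definable on a rising limb
  rising <- tibble::tibble(
    sf = c(8, 16), log10_sf = log10(c(8, 16)),
    log10_sensitivity = c(0.2, 0.4)
  )
  expect_error(compute_csf_acuity(rising), "descending")
})

test_that("SF threshold at 80% contrast hits the matching crossing", {
  # last point exactly at log10(1/0.8): returns 16 cpd
  pts <- tibble::tibble(
    sf = c(8, 16), log10_sf = log10(c(8, 16)),
    log10_sensitivity = c(0.5969, log10(1 / 0.8))
  )
  expect_equal(
    as.numeric(compute_sf_threshold_at_contrast(pts, 0.80)), 16,
    tolerance = 1e-9
  )
  # probe contrast 1 reduces to linear CSF acuity
  pts2 <- tibble::tibble(
    sf = c(8, 16), log10_sf = log10(c(8, 16)),
    log10_sensitivity = c(0.4, -0.2)
  )
  expect_equal(
    as.numeric(compute_sf_threshold_at_contrast(pts2, 1)),
    10^as.numeric(compute_csf_acuity(pts2)),
    tolerance = 1e-12
  )
})

test_that("summaries recover a generative log-parabola CSF", {
  # a CSF whose cut-off falls inside the measured grid, so the
  # crossing is interpolated rather than extrapolated
  csf <- true_csf(
    peak_gain = 14, peak_sf = 2.5, log_bandwidth = 0.8,
    low_freq_truncation = 0.5
  )
  sfs <- c(0.5, 1, 2, 4, 8, 12, 16)
  pts <- tibble::tibble(
    sf = sfs, log10_sf = log10(sfs),
    log10_sensitivity = log10(csf_sensitivity(csf, sfs))
  )
  # generative zero crossing of the parabola (high side, unfloored)
  true_acuity <- log10(2.5) + 0.8 * sqrt(log10(14) / (4 * log10(2)))
  acu <- compute_csf_acuity(pts)
  expect_equal(as.numeric(acu), true_acuity, tolerance = 0.05)
  # 80%-contrast crossing within 5%
  target <- log10(1 / 0.8)
  true_sf80 <- 10^(log10(2.5) +
    0.8 * sqrt((log10(14) - target) / (4 * log10(2))))
  sf80 <- compute_sf_threshold_at_contrast(pts, 0.80)
  expect_equal(as.numeric(sf80), true_sf80, tolerance = 0.05 * true_sf80)
  # summary row is self-consistent
  sm <- csf_summary(pts)
  expect_equal(sm$csf_acuity, as.numeric(acu))
  expect_true(sm$aulcsf > 0)
  expect_lte(sm$sf_threshold_80, 10^sm$csf_acuity + 1e-9)
})

test_that("the 80% crossing precedes the 100% crossing on a falling limb", {
  set.seed(17)
  for (i in 1:20) {
    csf <- true_csf(
      peak_gain = 10^runif(1, 1.2, 1.9),
      peak_sf = runif(1, 2, 4),
      log_bandwidth = runif(1, 0.7, 1.1)
    )
    sfs <- c(0.5, 1, 2, 4, 8, 12, 16)
    pts <- tibble::tibble(
      sf = sfs, log10_sf = log10(sfs),
      log10_sensitivity = log10(csf_sensitivity(csf, sfs))
    )
    sm <- csf_summary(pts)
    expect_lte(sm$sf_threshold_80, 10^sm$csf_acuity + 1e-9)
  }
})
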