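#' Truncated log-parabola contrast sensitivity function
#'
#' Generative description of an observer's contrast sensitivity along
#' one meridian. Sensitivity follows the standard log-parabola in
#' log10 spatial frequency,
#' \deqn{\log_{10} S(f) = \log_{10} G - 4 \log_{10}(2)
#'   \left(\frac{\log_{10}(f / f_c)}{B}\right)^2,}
#' with peak gain \eqn{G}, peak frequency \eqn{f_c} (cycles/degree) and
#' full bandwidth at half height \eqn{B} (log10 units). On the
#' low-frequency side the parabola is floored at
#' `low_freq_truncation * peak_gain`, reproducing the shallow low-SF
#' plateau of empirical CSFs.
#'
#' @param peak_gain Peak sensitivity (dimensionless, > 1).
#' @param peak_sf Spatial frequency of the peak, cycles/degree.
#' @param log_bandwidth Full width at half height, in log10 spatial
#'   frequency units (1 log10 unit is about 3.32 octaves).
#' @param low_freq_truncation Low-frequency plateau as a fraction of
#'   the peak gain, in `[0, 1]`.
#' @return An object of class `true_csf`.
#' @examples
#' csf <- true_csf(peak_gain = 100, peak_sf = 2, log_bandwidth = 2)
#' csf_sensitivity(csf, 2) # == 100 at the peak
#' @export
true_csf <- function(peak_gain = 45, peak_sf = 3, log_bandwidth = 0.9,
                     low_freq_truncation = 0.5) {
  check_scalar(peak_gain, "peak_gain", lower = 1, open_lower = TRUE)
  check_scalar(peak_sf, "peak_sf", lower = 0, open_lower = TRUE)
  check_scalar(log_bandwidth, "log_bandwidth", lower = 0, open_lower = TRUE)
  check_scalar(low_freq_truncation, "low_freq_truncation", 0, 1)
  structure(
    list(
      peak_gain = peak_gain, peak_sf = peak_sf,
      log_bandwidth = log_bandwidth,
      low_freq_truncation = low_freq_truncation
    ),
    class = "true_csf"
  )
}

#' Evaluate a generative CSF
#'
#' @param csf A [true_csf()] object.
#' @param sf Spatial frequencies, cycles/degree (all > 0).
#' @return Sensitivities (dimensionless, > 0), same length as `sf`.
#' @export
csf_sensitivity <- function(csf, sf) {
  stopifnot(inherits(csf, "true_csf"))
  if (!is.numeric(sf) || any(!is.finite(sf)) || any(sf <= 0)) {
    abort("`sf` must be positive and finite (cycles/degree).")
  }
  log_peak <- log10(csf$peak_gain)
  log_par <- log_peak -
    4 * log10(2) * (log10(sf / csf$peak_sf) / csf$log_bandwidth)^2
  floor_log <- log10(csf$low_freq_truncation) + log_peak
  out <- ifelse(sf < csf$peak_sf & csf$low_freq_truncation > 0,
    pmax(log_par, floor_log), log_par
  )
  10^out
}

#' @export
print.true_csf <- function(x, ...) {
  cat(sprintf(
    "<true_csf> peak %g at %g cpd, bandwidth %g log10 units, truncation %g\n",
    x$peak_gain, x$peak_sf, x$log_bandwidth, x$low_freq_truncation
  ))
  invisible(x)
}

#' Synthetic observer with a strong/weak meridian asymmetry
#'
#' Bundles the generative truth for one simulated eye: a CSF per
#' meridian, the Weibull psychometric parameters driving its
#' two-interval forced-choice (2IFC) decisions, and the generative
#' sweep-VEP threshold and response amplitude per meridian.
#'
#' The 2IFC guess rate is fixed at 0.5 (two alternatives). When the two
#' meridians are configured with a disparity, the weak-meridian CSF
#' must lie at or below the strong-meridian CSF at every spatial
#' frequency; this is checked on a dense grid at construction.
#'
#' @param csf_strong,csf_weak [true_csf()] objects for the strong and
#'   weak meridian (default: weak identical to strong, i.e. no
#'   disparity).
#' @param psychometric_slope Weibull slope (beta, > 0).
#' @param lapse_rate Lapse probability in `[0, 0.1]`.
#' @param vep_threshold_strong,vep_threshold_weak Generative sVEP
#'   spatial-frequency thresholds, cycles/degree (> 2).
#' @param vep_peak_amplitude Second-harmonic response amplitude at the
#'   first swept frequency, microvolts.
#' @param response_phase Response phase at the second harmonic, radians.
#' @return An object of class `observer_model`.
#' @examples
#' obs <- observer_model()
#' true_sensitivity(obs, sf = 4, meridian = "strong")
#' @export
observer_model <- function(csf_strong = true_csf(),
                           csf_weak = csf_strong,
                           psychometric_slope = 3,
                           lapse_rate = 0.02,
                           vep_threshold_strong = 19,
                           vep_threshold_weak = 16.5,
                           vep_peak_amplitude = 4,
                           response_phase = 1) {
  stopifnot(inherits(csf_strong, "true_csf"), inherits(csf_weak, "true_csf"))
  check_scalar(psychometric_slope, "psychometric_slope",
    lower = 0, open_lower = TRUE
  )
  check_scalar(lapse_rate, "lapse_rate", 0, 0.1)
  check_scalar(vep_threshold_strong, "vep_threshold_strong",
    lower = 2, open_lower = TRUE
  )
  check_scalar(vep_threshold_weak, "vep_threshold_weak",
    lower = 2, open_lower = TRUE
  )
  check_scalar(vep_peak_amplitude, "vep_peak_amplitude", lower = 0)
  check_scalar(response_phase, "response_phase")
  grid <- 10^seq(log10(0.125), log10(64), length.out = 200)
  if (any(csf_sensitivity(csf_weak, grid) >
    csf_sensitivity(csf_strong, grid) * (1 + 1e-9))) {
    abort("weak-meridian sensitivity exceeds strong-meridian sensitivity.")
  }
  structure(
    list(
      csf_strong = csf_strong, csf_weak = csf_weak,
      psychometric_slope = psychometric_slope,
      guess_rate = 0.5, lapse_rate = lapse_rate,
      vep_threshold_strong = vep_threshold_strong,
      vep_threshold_weak = vep_threshold_weak,
      vep_peak_amplitude = vep_peak_amplitude,
      response_phase = response_phase
    ),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat("<observer_model>\n")
  cat(sprintf(
    "  strong: peak %g @ %g cpd | weak: peak %g @ %g cpd\n",
    x$csf_strong$peak_gain, x$csf_strong$peak_sf,
    x$csf_weak$peak_gain, x$csf_weak$peak_sf
  ))
  cat(sprintf(
    "  Weibull slope %g, lapse %g | sVEP thresholds %g / %g cpd\n",
    x$psychometric_slope, x$lapse_rate,
    x$vep_threshold_strong, x$vep_threshold_weak
  ))
  invisible(x)
}

match_meridian <- function(meridian) {
  match.arg(meridian, c("strong", "weak"))
}

#' Generative sensitivity of an observer at one spatial frequency
#'
#' @param observer An [observer_model()].
#' @param sf Spatial frequencies, cycles/degree (> 0).
#' @param meridian `"strong"` or `"weak"`.
#' @return Sensitivities, same length as `sf`.
#' @export
true_sensitivity <- function(observer, sf, meridian = c("strong", "weak")) {
  stopifnot(inherits(observer, "observer_model"))
  meridian <- match_meridian(meridian)
  csf <- if (meridian == "strong") observer$csf_strong else observer$csf_weak
  csf_sensitivity(csf, sf)
}

#' Probability of a correct 2IFC response
#'
#' The observer detects a grating of given contrast with Weibull
#' probability and otherwise guesses:
#' \deqn{P(\mathrm{correct}) = \gamma + (1 - \gamma - \lambda)
#'   \left[1 - e^{-(c/\alpha)^\beta}\right],}
#' where \eqn{\gamma = 0.5} is the guess rate, \eqn{\lambda} the lapse
#' rate, \eqn{\alpha = 1 / S(f)} the contrast threshold and \eqn{\beta}
#' the psychometric slope.
#'
#' @inheritParams true_sensitivity
#' @param contrast Grating contrast(s), in `(0, 1]`.
#' @return Probabilities, same length as `contrast`.
#' @export
p_correct_2ifc <- function(observer, sf, contrast,
                           meridian = c("strong", "weak")) {
  stopifnot(inherits(observer, "observer_model"))
  meridian <- match_meridian(meridian)
  if (!is.numeric(contrast) || any(!is.finite(contrast)) ||
    any(contrast <= 0) || any(contrast > 1)) {
    abort("`contrast` must lie in (0, 1].")
  }
  alpha <- 1 / true_sensitivity(observer, sf, meridian)
  w <- 1 - exp(-(contrast / alpha)^observer$psychometric_slope)
  observer$guess_rate +
    (1 - observer$guess_rate - observer$lapse_rate) * w
}

#' Simulate one (or more) 2IFC trials
#'
#' Draws Bernoulli outcomes from [p_correct_2ifc()] using the current
#' RNG stream.
#'
#' @inheritParams p_correct_2ifc
#' @return Logical vector: `TRUE` for a correct response.
#' @export
simulate_2ifc_trial <- function(observer, sf, contrast,
                                meridian = c("strong", "weak")) {
  p <- p_correct_2ifc(observer, sf, contrast, meridian)
  runif(length(p)) < p
}

#' Generative contrast threshold at a given performance level
#'
#' Inverts the Weibull psychometric function of an observer to the
#' contrast yielding a target proportion correct. The three-down
#' one-up staircase with log-symmetric steps converges to
#' \eqn{(1/2)^{1/3} \approx 0.7937} correct, so the default level is
#' 0.793 — the generative truth that staircase threshold estimates are
#' compared against.
#'
#' @inheritParams true_sensitivity
#' @param level Target proportion correct, strictly between the guess
#'   rate and `1 - lapse_rate`.
#' @return Contrast (fraction).
#' @export
threshold_at_level <- function(observer, sf, meridian = c("strong", "weak"),
                               level = 0.793) {
  stopifnot(inherits(observer, "observer_model"))
  meridian <- match_meridian(meridian)
  g <- observer$guess_rate
  l <- observer$lapse_rate
  check_scalar(level, "level",
    lower = g, upper = 1 - l,
    open_lower = TRUE, open_upper = TRUE
  )
  w <- (level - g) / (1 - g - l)
  alpha <- 1 / true_sensitivity(observer, sf, meridian)
  alpha * (-log(1 - w))^(1 / observer$psychometric_slope)
}

#' Cohort specification for the synthetic study
#'
#' Describes the two groups of the emulated study design: astigmats
#' with normal corrected acuity (`AST`, 20 eyes) and meridional
#' amblyopes (`MA`, 19 eyes). Each eye gets a base (strong-meridian)
#' CSF drawn around group means and a weak-meridian CSF derived from it
#' by a per-eye peak-gain drop (log10 units) and bandwidth narrowing —
#' a construction that keeps weak sensitivity at or below strong
#' sensitivity at every frequency. The MA group is configured with a
#' larger mean generative disparity than the AST group.
#'
#' @param groups Data frame with one row per group. Defaults emulate
#'   the study design (group sizes 20 and 19 eyes; larger MA
#'   disparity). Columns: `group`, `n_eyes`, `log_gain_mean`,
#'   `log_gain_sd`, `peak_sf_mean`, `log_peak_sf_sd`, `bandwidth_mean`,
#'   `bandwidth_sd`, `gain_drop_mean`, `gain_drop_sd`, `bw_ratio_mean`,
#'   `bw_ratio_sd`, `vep_threshold_mean`, `vep_threshold_sd`,
#'   `vep_disparity_mean`, `vep_disparity_sd`.
#' @param psychometric_slope,lapse_rate Observer psychometric
#'   parameters shared by all eyes.
#' @param vep_peak_amplitude Generative sVEP response amplitude at the
#'   first swept frequency, microvolts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL,
                        psychometric_slope = 3,
                        lapse_rate = 0.02,
                        vep_peak_amplitude = 4) {
  if (is.null(groups)) {
    groups <- tibble(
      group = c("AST", "MA"),
      n_eyes = c(20L, 19L),
      log_gain_mean = c(1.65, 1.50),
      log_gain_sd = c(0.12, 0.15),
      peak_sf_mean = c(3, 3),
      log_peak_sf_sd = c(0.08, 0.08),
      bandwidth_mean = c(0.9, 0.9),
      bandwidth_sd = c(0.08, 0.08),
      gain_drop_mean = c(0.12, 0.24),
      gain_drop_sd = c(0.06, 0.08),
      bw_ratio_mean = c(0.95, 0.90),
      bw_ratio_sd = c(0.04, 0.04),
      vep_threshold_mean = c(19.2, 17.1),
      vep_threshold_sd = c(1.8, 1.8),
      vep_disparity_mean = c(2.6, 2.3),
      vep_disparity_sd = c(1.0, 1.0)
    )
  }
  groups <- as_tibble(groups)
  if (nrow(groups) < 1L) abort("`groups` must have at least one row.")
  if (any(groups$n_eyes <= 0)) abort("group sizes must be positive.")
  structure(
    list(
      groups = groups,
      psychometric_slope = psychometric_slope,
      lapse_rate = lapse_rate,
      vep_peak_amplitude = vep_peak_amplitude
    ),
    class = "cohort_spec"
  )
}

#' Serialize a cohort specification to JSON
#'
#' @param spec A [cohort_spec()].
#' @param path File path for the JSON document.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns the reconstructed [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(
    list(
      groups = spec$groups,
      psychometric_slope = spec$psychometric_slope,
      lapse_rate = spec$lapse_rate,
      vep_peak_amplitude = spec$vep_peak_amplitude
    ),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(
    groups = as_tibble(x$groups),
    psychometric_slope = x$psychometric_slope,
    lapse_rate = x$lapse_rate,
    vep_peak_amplitude = x$vep_peak_amplitude
  )
}

# draw from N(mean, sd) truncated to [lower, upper] by resampling;
# sd = 0 returns mean exactly
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  for (i in bad) {
    repeat {
      xi <- rnorm(1, mean, sd)
      if (xi >= lower && xi <= upper) break
    }
    x[i] <- xi
  }
  x
}

#' Generate a reproducible synthetic cohort of eyes
#'
#' Draws one [observer_model()] per eye from a [cohort_spec()]. Under
#' the default specification the MA group has a larger mean generative
#' meridional disparity (of both AULCSF and sVEP threshold) than the
#' AST group.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort
#'   exactly.
#' @return A tibble with one row per eye: `eye_id`, `group`, generative
#'   scalar columns (`gain_drop`, `bw_ratio`, `vep_threshold_strong`,
#'   `vep_threshold_weak`) and an `observer` list-column of
#'   [observer_model()] objects.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    rows <- purrr::pmap(spec$groups, function(group, n_eyes, log_gain_mean,
                                              log_gain_sd, peak_sf_mean,
                                              log_peak_sf_sd, bandwidth_mean,
                                              bandwidth_sd, gain_drop_mean,
                                              gain_drop_sd, bw_ratio_mean,
                                              bw_ratio_sd, vep_threshold_mean,
                                              vep_threshold_sd,
                                              vep_disparity_mean,
                                              vep_disparity_sd, ...) {
      n <- as.integer(n_eyes)
      log_gain <- rtrunc_norm(n, log_gain_mean, log_gain_sd, lower = 0.5)
      peak_sf <- 10^rtrunc_norm(
        n, log10(peak_sf_mean), log_peak_sf_sd,
        lower = log10(0.5), upper = log10(8)
      )
      bw <- rtrunc_norm(n, bandwidth_mean, bandwidth_sd, lower = 0.4)
      gain_drop <- rtrunc_norm(n, gain_drop_mean, gain_drop_sd, lower = 0)
      bw_ratio <- rtrunc_norm(n, bw_ratio_mean, bw_ratio_sd,
        lower = 0.5, upper = 1
      )
      vep_strong <- rtrunc_norm(n, vep_threshold_mean, vep_threshold_sd,
        lower = 6, upper = 30
      )
      vep_disp <- rtrunc_norm(n, vep_disparity_mean, vep_disparity_sd,
        lower = 0
      )
      vep_weak <- pmax(vep_strong - vep_disp, 2.5)
      observers <- lapply(seq_len(n), function(i) {
        strong <- true_csf(
          peak_gain = 10^log_gain[i], peak_sf = peak_sf[i],
          log_bandwidth = bw[i]
        )
        weak <- true_csf(
          peak_gain = 10^(log_gain[i] - gain_drop[i]),
          peak_sf = peak_sf[i],
          log_bandwidth = bw[i] * bw_ratio[i]
        )
        observer_model(
          csf_strong = strong, csf_weak = weak,
          psychometric_slope = spec$psychometric_slope,
          lapse_rate = spec$lapse_rate,
          vep_threshold_strong = vep_strong[i],
          vep_threshold_weak = vep_weak[i],
          vep_peak_amplitude = spec$vep_peak_amplitude
        )
      })
      tibble(
        group = group,
        gain_drop = gain_drop,
        bw_ratio = bw_ratio,
        vep_threshold_strong = vep_strong,
        vep_threshold_weak = vep_weak,
        observer = observers
      )
    })
    out <- purrr::list_rbind(rows)
    out$eye_id <- sprintf("eye%02d", seq_len(nrow(out)))
    dplyr::relocate(out, "eye_id", "group")
  })
}
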