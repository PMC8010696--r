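#' Configuration of the 3-down-1-up contrast staircase
#'
#' The staircase decreases contrast by 10% (multiplies by
#' `step_down_factor = 0.9`) after every three consecutive correct
#' responses and increases it after every error. The default up-step is
#' the reciprocal `1 / 0.9`, i.e. log-symmetric with the down-step,
#' which preserves the canonical 79.3% convergence level of the
#' 3-down-1-up rule; set `step_up_factor = 1.1` for a literal
#' "+10%" step.
#'
#' @param n_trials Trials per staircase block (>= 20; default 100).
#' @param step_down_factor Multiplicative down-step in `(0, 1)`.
#' @param step_up_factor Multiplicative up-step (> 1).
#' @param start_contrast Starting contrast (fraction).
#' @param contrast_floor,contrast_ceiling Clipping bounds on contrast.
#' @param sf_grid Spatial frequencies (cycles/degree) of a full CSF
#'   session, strictly increasing.
#' @param discard_reversals Rule for discarding early reversals before
#'   averaging: `"parity"` (drop the first 4 if that leaves an even
#'   count, else the first 3 — always retaining an even number),
#'   `"first4"`, `"first3"` or `"none"`.
#' @param average Average the retained reversal contrasts on a log10
#'   (`"geometric"`, default: the staircase is multiplicative) or
#'   linear (`"arithmetic"`) scale.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(n_trials = 100,
                             step_down_factor = 0.9,
                             step_up_factor = 1 / 0.9,
                             start_contrast = 0.5,
                             contrast_floor = 1e-4,
                             contrast_ceiling = 1,
                             sf_grid = c(0.5, 1, 2, 4, 8, 12, 16),
                             discard_reversals = c(
                               "parity", "first4",
                               "first3", "none"
                             ),
                             average = c("geometric", "arithmetic")) {
  check_scalar(n_trials, "n_trials", lower = 20)
  check_scalar(step_down_factor, "step_down_factor", 0, 1,
    open_lower = TRUE, open_upper = TRUE
  )
  check_scalar(step_up_factor, "step_up_factor", lower = 1, open_lower = TRUE)
  check_scalar(start_contrast, "start_contrast", 0, 1, open_lower = TRUE)
  check_scalar(contrast_floor, "contrast_floor", 0, 1, open_lower = TRUE)
  check_scalar(contrast_ceiling, "contrast_ceiling", contrast_floor, 1,
    open_lower = TRUE
  )
  if (any(diff(sf_grid) <= 0)) abort("`sf_grid` must be strictly increasing.")
  structure(
    list(
      n_trials = as.integer(n_trials),
      step_down_factor = step_down_factor,
      step_up_factor = step_up_factor,
      start_contrast = start_contrast,
      contrast_floor = contrast_floor,
      contrast_ceiling = contrast_ceiling,
      sf_grid = sf_grid,
      discard_reversals = match.arg(discard_reversals),
      average = match.arg(average)
    ),
    class = "staircase_config"
  )
}

#' Run one 3-down-1-up staircase block
#'
#' Simulates `n_trials` 2IFC trials of an [observer_model()] at a fixed
#' spatial frequency and meridian under the 3-down-1-up rule: contrast
#' is multiplied by `step_down_factor` after each run of three
#' consecutive correct responses (the run counter resets after every
#' step), and by `step_up_factor` after every error. Contrast is
#' clipped to `[contrast_floor, contrast_ceiling]`.
#'
#' @param observer An [observer_model()].
#' @param sf Spatial frequency of the block, cycles/degree.
#' @param meridian `"strong"` or `"weak"`.
#' @param config A [staircase_config()].
#' @param seed Optional integer seed for this block.
#' @return An object of class `staircase_run`: trial log (tibble with
#'   `trial`, `contrast`, `correct`), reversal indices and contrasts,
#'   `threshold_estimate` and `converged` flag. Use [tidy()] for the
#'   trial log and [glance()] for the one-row summary.
#' @examples
#' obs <- observer_model()
#' run <- run_staircase(obs, sf = 4, meridian = "strong", seed = 7)
#' glance(run)
#' @export
run_staircase <- function(observer, sf, meridian = c("strong", "weak"),
                          config = staircase_config(), seed = NULL) {
  stopifnot(inherits(observer, "observer_model"),
    inherits(config, "staircase_config"))
  meridian <- match_meridian(meridian)
  check_scalar(sf, "sf", lower = 0, open_lower = TRUE)
  alpha <- 1 / true_sensitivity(observer, sf, meridian)
  beta <- observer$psychometric_slope
  g <- observer$guess_rate
  l <- observer$lapse_rate
  n <- config$n_trials
  lo <- config$contrast_floor
  hi <- config$contrast_ceiling
  down <- config$step_down_factor
  up <- config$step_up_factor

  with_seed(seed, {
    u <- runif(n)
    contrast <- numeric(n)
    correct <- logical(n)
    c_now <- min(max(config$start_contrast, lo), hi)
    n_run <- 0L
    for (i in seq_len(n)) {
      contrast[i] <- c_now
      p <- g + (1 - g - l) * (1 - exp(-(c_now / alpha)^beta))
      ok <- u[i] < p
      correct[i] <- ok
      if (ok) {
        n_run <- n_run + 1L
        if (n_run == 3L) {
          c_now <- min(max(c_now * down, lo), hi)
          n_run <- 0L
        }
      } else {
        n_run <- 0L
        c_now <- min(max(c_now * up, lo), hi)
      }
    }
    trial_log <- tibble(
      trial = seq_len(n), contrast = contrast, correct = correct
    )
    rev_idx <- detect_reversals(trial_log)
    run <- structure(
      list(
        trial_log = trial_log,
        reversal_indices = rev_idx,
        reversal_contrasts = contrast[rev_idx],
        threshold_estimate = NA_real_,
        converged = FALSE,
        sf = sf, meridian = meridian, config = config
      ),
      class = "staircase_run"
    )
    est <- estimate_threshold(run, config)
    run$threshold_estimate <- est
    run$converged <- !is.na(est)
    run
  })
}

#' Locate staircase reversals
#'
#' A reversal is a trial at which the direction of the most recent
#' contrast change flips (from decreasing to increasing or vice versa);
#' the reported index is the turning point, i.e. the local extremum of
#' the contrast sequence. Trials before the first contrast step cannot
#' host a reversal.
#'
#' @param trial_log A `staircase_run` trial log (tibble with a
#'   `contrast` column) or a numeric contrast sequence.
#' @return Integer trial indices of the reversals.
#' @examples
#' detect_reversals(c(0.5, 0.45, 0.4, 0.45, 0.4)) # turns at trials 3 and 4
#' @export
detect_reversals <- function(trial_log) {
  contrasts <- if (is.data.frame(trial_log)) trial_log$contrast else trial_log
  if (length(contrasts) == 0L) abort("`trial_log` must be non-empty.")
  dc <- diff(contrasts)
  idx <- integer(0)
  last_dir <- 0
  for (i in seq_along(dc)) {
    d <- sign(dc[i])
    if (d == 0) next # clipped or repeated contrast: no direction change
    if (last_dir != 0 && d != last_dir) idx <- c(idx, i)
    last_dir <- d
  }
  idx
}

#' Estimate the contrast threshold from a staircase run
#'
#' Averages the contrasts of an even number of reversals after
#' discarding the first three or four (default rule: drop four if that
#' leaves an even count, otherwise three). The average is taken in
#' log10 contrast (geometric mean) by default, matching the
#' multiplicative step rule. Runs with fewer than six reversals are
#' flagged as non-converged and return `NA`.
#'
#' @param run A `staircase_run`, or a numeric vector of reversal
#'   contrasts.
#' @param config A [staircase_config()] (supplies the discard and
#'   averaging rules).
#' @return The estimated threshold contrast, or `NA_real_` if the run
#'   did not converge.
#' @export
estimate_threshold <- function(run, config = staircase_config()) {
  stopifnot(inherits(config, "staircase_config"))
  revs <- if (inherits(run, "staircase_run")) run$reversal_contrasts else run
  n <- length(revs)
  if (n < 6L) {
    return(NA_real_)
  }
  drop_n <- switch(config$discard_reversals,
    parity = if ((n - 4L) %% 2L == 0L) 4L else 3L,
    first4 = 4L,
    first3 = 3L,
    none = 0L
  )
  kept <- revs[seq.int(drop_n + 1L, n)]
  if (config$discard_reversals == "parity" && length(kept) %% 2L != 0L) {
    kept <- kept[-1L] # defensive; parity rule always leaves an even count
  }
  if (length(kept) < 2L) {
    return(NA_real_)
  }
  est <- switch(config$average,
    geometric = 10^mean(log10(kept)),
    arithmetic = mean(kept)
  )
  min(max(est, config$contrast_floor), config$contrast_ceiling)
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "<staircase_run> %g cpd, %s meridian: %d trials, %d reversals, %s\n",
    x$sf, x$meridian, nrow(x$trial_log), length(x$reversal_indices),
    if (x$converged) {
      sprintf("threshold %.4g", x$threshold_estimate)
    } else {
      "not converged"
    }
  ))
  invisible(x)
}

# Short practice pre-block emulating the demo run that precedes a
# real session: a coarse 2-down-1-up staircase (large multiplicative
# steps) that homes in on the threshold region quickly. Returns a
# starting contrast for the main block. With 10% steps and 100 trials
# a staircase started at 0.5 cannot reach a threshold of ~0.02 within
# the block, so the main measurement needs an informed start just as
# real sessions get one from the practice block.
warmup_start <- function(observer, sf, meridian, config,
                         n_trials = 25, step = 0.5, seed = NULL) {
  with_seed(seed, {
    c_now <- config$start_contrast
    lo <- config$contrast_floor
    track <- numeric(n_trials)
    n_run <- 0L
    for (i in seq_len(n_trials)) {
      track[i] <- c_now
      ok <- simulate_2ifc_trial(observer, sf, c_now, meridian)
      if (ok) {
        n_run <- n_run + 1L
        if (n_run == 2L) {
          c_now <- max(c_now * step, lo)
          n_run <- 0L
        }
      } else {
        n_run <- 0L
        c_now <- min(c_now / step, config$contrast_ceiling)
      }
    }
    last <- tail(track, 5)
    min(max(10^mean(log10(last)), lo), config$contrast_ceiling)
  })
}

#' Run a full CSF session (7 spatial frequencies x 2 meridians)
#'
#' Runs one staircase block per (spatial frequency, meridian) cell —
#' fourteen blocks of `n_trials` trials under the default
#' configuration — in randomized block order, as in a full
#' psychophysical session. By default each block is preceded by a
#' short coarse-step practice staircase (not part of the block's
#' trials) whose outcome sets the block's starting contrast, playing
#' the role of the practice run of a real session; without it a
#' 10%-step staircase started at 0.5 contrast cannot reach the
#' thresholds of the most sensitive cells within 100 trials.
#'
#' @inheritParams run_staircase
#' @param seed Integer seed; per-block substreams are derived from it,
#'   so individual blocks are reproducible in isolation.
#' @param warmup Run the practice pre-block per cell (default `TRUE`).
#' @return A tibble with one row per block: `block`, `sf`, `meridian`,
#'   `threshold`, `converged`, `n_reversals`, and a `run` list-column
#'   holding each [run_staircase()] result.
#' @export
run_csf_session <- function(observer, config = staircase_config(),
                            seed = NULL, warmup = TRUE) {
  cells <- tidyr::expand_grid(
    sf = config$sf_grid, meridian = c("strong", "weak")
  )
  order_seed <- if (is.null(seed)) NULL else substream_seed(seed, 0)
  cells <- with_seed(order_seed, cells[sample.int(nrow(cells)), ])
  cells$block <- seq_len(nrow(cells))
  runs <- purrr::pmap(cells, function(sf, meridian, block) {
    block_seed <- if (is.null(seed)) NULL else substream_seed(seed, 1, block)
    block_config <- config
    if (warmup) {
      warm_seed <- if (is.null(seed)) NULL else substream_seed(seed, 2, block)
      block_config$start_contrast <- warmup_start(
        observer, sf, meridian, config,
        seed = warm_seed
      )
    }
    run_staircase(observer, sf, meridian, block_config, seed = block_seed)
  })
  tibble(
    block = cells$block,
    sf = cells$sf,
    meridian = cells$meridian,
    threshold = purrr::map_dbl(runs, "threshold_estimate"),
    converged = purrr::map_lgl(runs, "converged"),
    n_reversals = purrr::map_int(runs, ~ length(.x$reversal_indices)),
    run = runs
  )
}
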