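#' Convert contrast thresholds to log CSF points
#'
#' Sensitivity is the reciprocal of the contrast threshold; both axes
#' of the CSF are handled in log10 units. Non-converged cells (missing
#' thresholds) are dropped and counted in the `n_dropped` attribute.
#'
#' @param thresholds A data frame with columns `sf` (cycles/degree) and
#'   `threshold` (contrast fraction in `(0, 1]`; `NA` marks a
#'   non-converged cell), plus an optional logical `converged` column.
#' @return A tibble sorted by `sf` with columns `sf`, `log10_sf`,
#'   `sensitivity`, `log10_sensitivity`; attribute `n_dropped` counts
#'   omitted cells.
#' @examples
#' thresholds_to_csf(data.frame(sf = 4, threshold = 0.01))
#' @export
thresholds_to_csf <- function(thresholds) {
  if (!is.data.frame(thresholds) || nrow(thresholds) == 0L) {
    abort("`thresholds` must be a non-empty data frame.")
  }
  if (!all(c("sf", "threshold") %in% names(thresholds))) {
    abort("`thresholds` needs columns `sf` and `threshold`.")
  }
  x <- as_tibble(thresholds)
  keep <- !is.na(x$threshold)
  if ("converged" %in% names(x)) keep <- keep & x$converged
  n_dropped <- sum(!keep)
  x <- x[keep, ]
  if (nrow(x) == 0L) abort("no converged thresholds to convert.")
  if (any(x$threshold <= 0 | x$threshold > 1)) {
    abort("thresholds must lie in (0, 1].")
  }
  if (any(x$sf <= 0)) abort("spatial frequencies must be positive.")
  out <- tibble(
    sf = x$sf,
    log10_sf = log10(x$sf),
    sensitivity = 1 / x$threshold,
    log10_sensitivity = log10(1 / x$threshold)
  )
  out <- dplyr::arrange(out, .data$sf)
  attr(out, "n_dropped") <- n_dropped
  out
}

# Evaluate the piecewise-linear log CSF at log10-sf positions `x`,
# extrapolating from the outer two points beyond the measured range.
# The high-side extrapolation slope is clamped to <= 0 so that an
# (unphysical) rising tail never inflates extrapolated values.
eval_log_csf <- function(x, xs, ys, clamp_high_slope = TRUE) {
  n <- length(xs)
  out <- numeric(length(x))
  lo_slope <- if (n >= 2) (ys[2] - ys[1]) / (xs[2] - xs[1]) else 0
  hi_slope <- if (n >= 2) (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1]) else 0
  if (clamp_high_slope) hi_slope <- min(hi_slope, 0)
  for (i in seq_along(x)) {
    xi <- x[i]
    if (xi <= xs[1]) {
      out[i] <- ys[1] + lo_slope * (xi - xs[1])
    } else if (xi >= xs[n]) {
      out[i] <- ys[n] + hi_slope * (xi - xs[n])
    } else {
      j <- findInterval(xi, xs)
      w <- (xi - xs[j]) / (xs[j + 1] - xs[j])
      out[i] <- ys[j] + w * (ys[j + 1] - ys[j])
    }
  }
  out
}

check_points <- function(points, min_points = 2L) {
  if (!is.data.frame(points) ||
    !all(c("log10_sf", "log10_sensitivity") %in% names(points))) {
    abort("`points` needs columns `log10_sf` and `log10_sensitivity`.")
  }
  pts <- as_tibble(points)
  pts <- pts[is.finite(pts$log10_sf) & is.finite(pts$log10_sensitivity), ]
  pts <- dplyr::arrange(pts, .data$log10_sf)
  if (anyDuplicated(pts$log10_sf)) {
    abort("duplicate spatial frequencies in `points`.")
  }
  if (nrow(pts) < min_points) {
    abort(sprintf("need at least %d converged CSF points.", min_points))
  }
  pts
}

#' Area under the log CSF (AULCSF)
#'
#' Trapezoidal integral of log10 sensitivity (floored at zero, i.e.
#' sensitivity 1) over log10 spatial frequency across a fixed band,
#' 1.5 to 18 cycles/degree by default. The measured grid (0.5-16 cpd)
#' does not span the band exactly, so the piecewise-linear curve is
#' extrapolated from the outer two points to reach the integration
#' bounds (high-side slope clamped to be non-positive). Segment
#' crossings of zero are split analytically, so the floor introduces no
#' discretisation error.
#'
#' @param points CSF points from [thresholds_to_csf()] (needs >= 3).
#' @param sf_range Integration band in cycles/degree.
#' @return The area, in log10-units squared (>= 0).
#' @examples
#' pts <- thresholds_to_csf(data.frame(
#'   sf = c(1, 4, 16), threshold = c(0.1, 0.1, 0.1)
#' ))
#' compute_aulcsf(pts) # = 1 * (log10(18) - log10(1.5))
#' @export
compute_aulcsf <- function(points, sf_range = c(1.5, 18)) {
  pts <- check_points(points, min_points = 3L)
  a <- log10(sf_range[1])
  b <- log10(sf_range[2])
  if (max(pts$log10_sf) < a || min(pts$log10_sf) > b) {
    abort("measured points do not overlap the integration band.")
  }
  xs <- pts$log10_sf
  ys <- pts$log10_sensitivity
  knots <- sort(unique(c(a, b, xs[xs > a & xs < b])))
  yk <- eval_log_csf(knots, xs, ys)
  area <- 0
  for (j in seq_len(length(knots) - 1L)) {
    x1 <- knots[j]
    x2 <- knots[j + 1L]
    y1 <- yk[j]
    y2 <- yk[j + 1L]
    if (y1 <= 0 && y2 <= 0) next
    if (y1 >= 0 && y2 >= 0) {
      area <- area + (x2 - x1) * (y1 + y2) / 2
    } else {
      # segment crosses the floor: integrate the positive triangle only
      xc <- x1 + (0 - y1) / (y2 - y1) * (x2 - x1)
      if (y1 > 0) {
        area <- area + (xc - x1) * y1 / 2
      } else {
        area <- area + (x2 - xc) * y2 / 2
      }
    }
  }
  area
}

# shared root-finder: log10 sf at which the (extrapolated) descending
# limb of the log CSF reaches `target` log10 sensitivity
descending_crossing <- function(points, target) {
  pts <- check_points(points, min_points = 2L)
  xs <- pts$log10_sf
  ys <- pts$log10_sensitivity
  n <- length(xs)
  if (ys[n] >= ys[n - 1]) {
    abort("no descending high-frequency limb: crossing undefined.")
  }
  peak <- which.max(ys)
  if (ys[peak] <= target) {
    abort("entire measured CSF lies below the target sensitivity.")
  }
  for (j in seq.int(peak, n - 1L)) {
    if (ys[j] >= target && ys[j + 1L] < target) {
      w <- (ys[j] - target) / (ys[j] - ys[j + 1L])
      return(list(x = xs[j] + w * (xs[j + 1L] - xs[j]), extrapolated = FALSE))
    }
  }
  # all measured points above target: extrapolate from the last two
  slope <- (ys[n] - ys[n - 1L]) / (xs[n] - xs[n - 1L])
  list(x = xs[n] + (target - ys[n]) / slope, extrapolated = TRUE)
}

#' CSF acuity: the 100%-contrast cut-off
#'
#' The spatial frequency at which the CSF's descending limb crosses
#' sensitivity 1 (log10 sensitivity 0, i.e. a contrast threshold of
#' 100%), by linear interpolation in log-log coordinates; when every
#' measured sensitivity exceeds 1 the crossing is extrapolated from the
#' last two points and flagged.
#'
#' @param points CSF points from [thresholds_to_csf()].
#' @return The acuity in log10 cycles/degree, with attribute
#'   `extrapolated` (logical).
#' @examples
#' pts <- thresholds_to_csf(data.frame(
#'   sf = c(8, 16), threshold = c(10^-0.3, 10^0.3 / 10)
#' ))
#' @export
compute_csf_acuity <- function(points) {
  cr <- descending_crossing(points, target = 0)
  structure(cr$x, extrapolated = cr$extrapolated)
}

#' Spatial-frequency threshold at a fixed contrast
#'
#' The spatial frequency at which a grating of the given contrast (80%
#' by default) is just detectable: the descending limb's crossing of
#' log10 sensitivity `log10(1/contrast)`. Reported in linear
#' cycles/degree. With `contrast = 1` this reduces to
#' `10^compute_csf_acuity(points)`.
#'
#' @param points CSF points from [thresholds_to_csf()].
#' @param contrast Probe contrast in `(0, 1]`.
#' @return Spatial frequency in cycles/degree, with attribute
#'   `extrapolated`.
#' @export
compute_sf_threshold_at_contrast <- function(points, contrast = 0.80) {
  check_scalar(contrast, "contrast", 0, 1, open_lower = TRUE)
  cr <- descending_crossing(points, target = log10(1 / contrast))
  structure(10^cr$x, extrapolated = cr$extrapolated)
}

#' One-row CSF summary (AULCSF, acuity, SF threshold at 80% contrast)
#'
#' @param thresholds Per-SF contrast thresholds as accepted by
#'   [thresholds_to_csf()], or an already-converted points tibble.
#' @param sf_range AULCSF integration band, cycles/degree.
#' @param contrast Probe contrast for the SF threshold.
#' @return A one-row tibble: `aulcsf`, `csf_acuity` (log10 cpd),
#'   `sf_threshold_80` (cpd), extrapolation flags and the number of
#'   points used.
#' @examples
#' thr <- data.frame(
#'   sf = c(0.5, 1, 2, 4, 8, 12, 16),
#'   threshold = c(0.06, 0.035, 0.025, 0.025, 0.04, 0.06, 0.14)
#' )
#' csf_summary(thr)
#' @export
csf_summary <- function(thresholds, sf_range = c(1.5, 18), contrast = 0.80) {
  pts <- if (all(c("log10_sf", "log10_sensitivity") %in% names(thresholds))) {
    as_tibble(thresholds)
  } else {
    thresholds_to_csf(thresholds)
  }
  # a summary row must survive degenerate measured CSFs (e.g. a noisy
  # non-descending tail): failed components become flagged NAs
  soft <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(NA_real_, extrapolated = NA)
    })
  }
  aul <- soft(compute_aulcsf(pts, sf_range))
  acuity <- soft(compute_csf_acuity(pts))
  sf80 <- soft(compute_sf_threshold_at_contrast(pts, contrast))
  tibble(
    aulcsf = as.numeric(aul),
    csf_acuity = as.numeric(acuity),
    sf_threshold_80 = as.numeric(sf80),
    acuity_extrapolated = attr(acuity, "extrapolated") %||% FALSE,
    sf80_extrapolated = attr(sf80, "extrapolated") %||% FALSE,
    n_points = nrow(pts)
  )
}
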