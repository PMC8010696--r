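#' Paired (within-group) meridional contrast
#'
#' One-sample t-test of the per-eye strong-minus-weak disparities of
#' one metric in one group: t = mean / SE with n - 1 degrees of
#' freedom and a two-sided p value.
#'
#' @param data A data frame containing the disparity column, or a bare
#'   numeric vector of disparities.
#' @param value Name of the disparity column (default `"disparity"`).
#' @return A one-row tibble: `estimate` (mean disparity), `se`,
#'   `statistic` (t), `df`, `p.value`, `n`.
#' @examples
#' paired_contrast(c(1, 2, 3)) # t = 2 * sqrt(3)
#' @export
paired_contrast <- function(data, value = "disparity") {
  x <- if (is.data.frame(data)) data[[value]] else data
  x <- x[is.finite(x)]
  if (length(x) < 3L) abort("paired contrast needs at least 3 eyes.")
  if (sd(x) == 0) {
    # degenerate but well-defined limits: t = 0 iff mean = 0
    return(tibble(
      estimate = mean(x), se = 0,
      statistic = if (mean(x) == 0) 0 else sign(mean(x)) * Inf,
      df = length(x) - 1, p.value = if (mean(x) == 0) 1 else 0,
      n = length(x)
    ))
  }
  tt <- t.test(x)
  tibble(
    estimate = unname(tt$estimate),
    se = unname(tt$stderr),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    n = length(x)
  )
}

#' Two-sample (between-group) contrast of disparities
#'
#' Pooled-variance two-sample t-test comparing per-eye disparities
#' between two groups, with n1 + n2 - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of per-eye disparities (or data frames
#'   with a `value` column) for the two groups.
#' @param value Column name when data frames are supplied.
#' @return A one-row tibble: `estimate` (mean difference x - y), `se`,
#'   `statistic`, `df`, `p.value`, `n1`, `n2`.
#' @export
group_contrast <- function(x, y, value = "disparity") {
  xa <- if (is.data.frame(x)) x[[value]] else x
  yb <- if (is.data.frame(y)) y[[value]] else y
  xa <- xa[is.finite(xa)]
  yb <- yb[is.finite(yb)]
  if (length(xa) < 3L || length(yb) < 3L) {
    abort("each group needs at least 3 eyes.")
  }
  if (sd(xa) == 0 && sd(yb) == 0) {
    abort("degenerate (zero) variance in both groups.")
  }
  tt <- t.test(xa, yb, var.equal = TRUE)
  tibble(
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    se = unname(tt$stderr),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    n1 = length(xa), n2 = length(yb)
  )
}

#' Pearson correlation between two metrics
#'
#' @param data A data frame holding both metric columns.
#' @param x,y Column names (strings) or bare column names.
#' @return A one-row tibble: `r`, `statistic`, `df`, `p.value`, `n`.
#' @examples
#' correlate_metrics(data.frame(a = 1:10, b = (1:10)^2), "a", "b")
#' @export
correlate_metrics <- function(data, x, y) {
  xv <- if (is.character(x)) data[[x]] else rlang::eval_tidy(enquo(x), data)
  yv <- if (is.character(y)) data[[y]] else rlang::eval_tidy(enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 4L) abort("correlation needs at least 4 paired values.")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance in a metric.")
  ct <- cor.test(xv, yv, method = "pearson")
  tibble(
    r = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value,
    n = length(xv)
  )
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for each p value, for a family of `m` comparisons
#' (`m` defaults to the number of p values and may not be smaller).
#'
#' @param p Numeric vector of p values.
#' @param m Family size.
#' @return Adjusted p values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 7)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1].")
  if (m < length(p)) abort("`m` must be at least the number of p values.")
  pmin(1, p * m)
}

#' Meridional disparity report (strong vs weak, per group and metric)
#'
#' Builds the group-level summary table of the study: for every
#' (group, metric) cell, the strong- and weak-meridian means with
#' standard errors, the per-eye difference (strong minus weak) with
#' its standard error, and the paired t-test of that difference. For
#' complete data the difference of the means equals the mean of the
#' per-eye differences.
#'
#' @param data A data frame with columns `eye_id`, `group`, `metric`,
#'   `strong`, `weak` (one row per eye and metric).
#' @param adjust `"none"` or `"bonferroni"`; when adjusting, the
#'   family is the set of metrics within each group (or supply
#'   `adjust_m`).
#' @param adjust_m Optional explicit family size for the adjustment.
#' @return A `disparity_report` tibble with columns `group`, `metric`,
#'   `n`, `strong_mean`, `strong_se`, `weak_mean`, `weak_se`,
#'   `diff_mean`, `diff_se`, `statistic`, `df`, `p.value` (and
#'   `adjusted_p` when requested).
#' @export
build_disparity_report <- function(data, adjust = c("none", "bonferroni"),
                                   adjust_m = NULL) {
  adjust <- match.arg(adjust)
  need <- c("eye_id", "group", "metric", "strong", "weak")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort("`data` needs columns eye_id, group, metric, strong, weak.")
  }
  if (nrow(data) == 0L) abort("empty disparity data.")
  se <- function(v) sd(v) / sqrt(length(v))
  dat <- data |>
    dplyr::mutate(disparity = .data$strong - .data$weak) |>
    dplyr::filter(is.finite(.data$disparity)) |>
    dplyr::group_by(.data$group, .data$metric) |>
    # a contrast needs >= 3 eyes; thinner cells (non-converged or
    # pairwise-excluded eyes) are omitted from the report
    dplyr::filter(dplyr::n() >= 3L)
  if (nrow(dat) == 0L) {
    out <- tibble(
      group = character(0), metric = character(0), n = integer(0),
      strong_mean = numeric(0), strong_se = numeric(0),
      weak_mean = numeric(0), weak_se = numeric(0),
      diff_mean = numeric(0), diff_se = numeric(0),
      statistic = numeric(0), df = numeric(0), p.value = numeric(0)
    )
    class(out) <- c("disparity_report", class(out))
    return(out)
  }
  out <- dplyr::reframe(dat, {
    disp <- .data$disparity
    s <- .data$strong
    w <- .data$weak
    ct <- paired_contrast(disp)
    tibble(
      n = length(disp),
      strong_mean = mean(s), strong_se = se(s),
      weak_mean = mean(w), weak_se = se(w),
      diff_mean = ct$estimate, diff_se = ct$se,
      statistic = ct$statistic, df = ct$df, p.value = ct$p.value
    )
  })
  if (adjust == "bonferroni") {
    out <- out |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(adjusted_p = bonferroni(
        .data$p.value, m = adjust_m %||% dplyr::n()
      )) |>
      dplyr::ungroup()
  }
  class(out) <- c("disparity_report", class(out))
  out
}
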