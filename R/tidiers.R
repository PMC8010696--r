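#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a staircase run into its trial log
#'
#' @param x A `staircase_run`.
#' @param ... Unused.
#' @return The trial log tibble (`trial`, `contrast`, `correct`) with
#'   a logical `reversal` column marking turning points.
#' @export
tidy.staircase_run <- function(x, ...) {
  log <- x$trial_log
  log$reversal <- log$trial %in% x$reversal_indices
  log
}

#' One-row summary of a staircase run
#'
#' @param x A `staircase_run`.
#' @param ... Unused.
#' @return A one-row tibble: `sf`, `meridian`, `n_trials`,
#'   `n_reversals`, `threshold`, `converged`, `prop_correct`.
#' @export
glance.staircase_run <- function(x, ...) {
  tibble(
    sf = x$sf, meridian = x$meridian,
    n_trials = nrow(x$trial_log),
    n_reversals = length(x$reversal_indices),
    threshold = x$threshold_estimate,
    converged = x$converged,
    prop_correct = mean(x$trial_log$correct)
  )
}

#' Tidy an sVEP threshold fit into its per-epoch table
#'
#' @param x A `vep_fit`.
#' @param ... Unused.
#' @return The sweep response tibble with an `included` column marking
#'   the scoring-window epochs.
#' @export
tidy.vep_fit <- function(x, ...) {
  resp <- x$response
  resp$included <- resp$epoch %in% x$included_epochs
  resp
}

#' One-row summary of an sVEP threshold fit
#'
#' @param x A `vep_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `threshold`, `slope`, `intercept`,
#'   `n_window`, `criterion_snr`, `valid`, `reason`.
#' @export
glance.vep_fit <- function(x, ...) {
  tibble(
    threshold = x$threshold, slope = x$slope, intercept = x$intercept,
    n_window = length(x$included_epochs),
    criterion_snr = x$criterion_snr,
    valid = x$valid, reason = x$reason
  )
}
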