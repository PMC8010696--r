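#' Derive a reproducible substream seed
#'
#' Mixes a master seed with a sequence of integer tags (stage, unit,
#' repetition, ...) into a new seed in `[1, 2^31 - 2]`. The pipeline
#' fans a single master seed out to per-eye, per-block and per-trial
#' substreams through this function, so any stage can be re-run in
#' isolation and reproduce the exact stream it saw inside a full run.
#'
#' @param seed Master integer seed.
#' @param ... Integer tags identifying the substream (order matters).
#' @return A single integer seed.
#' @examples
#' substream_seed(1, 2, 7)
#' @export
substream_seed <- function(seed, ...) {
  tags <- c(...)
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- as.double(seed %% m)
  for (k in as.double(tags)) {
    # affine mix; multipliers small enough that products stay < 2^53
    h <- (h * 69069 + (k %% m) * 10007 + 12345) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the ambient RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# scalar numeric validator
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}
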