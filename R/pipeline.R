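#' End-to-end study configuration
#'
#' Bundles every knob of a full simulated study: the cohort, the
#' staircase, the sweep stimulus, the EEG noise model and the sVEP
#' analysis constants. A single master `seed` fans out to per-eye,
#' per-block and per-trial substreams (via [substream_seed()]), so the
#' whole run — and any stage of it in isolation — is reproducible.
#'
#' @param seed Master integer seed.
#' @param cohort A [cohort_spec()].
#' @param staircase A [staircase_config()].
#' @param stimulus A [sweep_stimulus()].
#' @param noise A [noise_config()].
#' @param criterion_snr sVEP SNR validity criterion.
#' @param noise_offsets Noise-bin offsets from the signal frequency,
#'   Hz.
#' @param forgetting_factor RLS memory constant.
#' @param eye_mode `"all"` retains both eyes of the emulated design;
#'   `"random-one"` keeps one random eye per subject-like pair.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       cohort = cohort_spec(),
                       staircase = staircase_config(),
                       stimulus = sweep_stimulus(),
                       noise = noise_config(),
                       criterion_snr = 3,
                       noise_offsets = c(-1, 1),
                       forgetting_factor = 0.9995,
                       eye_mode = c("all", "random-one")) {
  stopifnot(
    inherits(cohort, "cohort_spec"),
    inherits(staircase, "staircase_config"),
    inherits(stimulus, "sweep_stimulus"),
    inherits(noise, "noise_config")
  )
  structure(
    list(
      seed = as.integer(seed), cohort = cohort, staircase = staircase,
      stimulus = stimulus, noise = noise, criterion_snr = criterion_snr,
      noise_offsets = noise_offsets, forgetting_factor = forgetting_factor,
      eye_mode = match.arg(eye_mode)
    ),
    class = "run_config"
  )
}

# stage tags for seed fan-out
.stage <- c(cohort = 101L, csf = 202L, svep = 303L)

# CSF chain for one eye: 14-block session -> per-meridian summaries
run_eye_csf <- function(observer, config, eye_index) {
  session <- run_csf_session(
    observer, config$staircase,
    seed = substream_seed(config$seed, .stage[["csf"]], eye_index)
  )
  thresholds <- session[, c("block", "sf", "meridian", "threshold",
    "converged", "n_reversals")]
  summaries <- thresholds |>
    dplyr::group_by(.data$meridian) |>
    dplyr::group_modify(function(d, key) {
      csf_summary(d)
    }) |>
    dplyr::ungroup()
  trial_logs <- purrr::pmap(
    session[, c("block", "sf", "meridian", "run")],
    function(block, sf, meridian, run) {
      dplyr::mutate(run$trial_log,
        block = block, sf_cpd = sf, meridian = meridian,
        .before = 1
      )
    }
  ) |> purrr::list_rbind()
  list(
    thresholds = thresholds, summaries = summaries,
    trial_logs = trial_logs
  )
}

# sVEP chain for one eye: generate repeated trials and analyse both
# meridians
run_eye_svep <- function(observer, config, eye_index) {
  res <- lapply(c("strong", "weak"), function(m) {
    m_tag <- if (m == "strong") 1L else 2L
    trials <- lapply(seq_len(config$stimulus$n_repeats), function(r) {
      generate_sweep_trial(
        observer, config$stimulus, m, config$noise,
        seed = substream_seed(
          config$seed, .stage[["svep"]], eye_index, m_tag, r
        )
      )
    })
    out <- analyze_sweep_trials(
      trials,
      criterion_snr = config$criterion_snr,
      noise_offsets = config$noise_offsets,
      forgetting_factor = config$forgetting_factor
    )
    out$response$meridian <- m
    out
  })
  names(res) <- c("strong", "weak")
  res
}

#' Run the full simulated study
#'
#' Simulates the cohort, runs the complete CSF chain (14 staircase
#' blocks per eye, CSF summaries) and the complete sVEP chain
#' (repeated sweep trials, RLS harmonic extraction, coherent
#' averaging, SNR-gated regression thresholds) for every eye, and
#' assembles the meridional-disparity report. Eyes whose sVEP fits do
#' not pass the regression criteria on both meridians are excluded
#' pairwise from the sVEP-threshold rows, mirroring the analysis
#' design.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all result tables
#'   are written as CSV together with a `manifest.json` recording the
#'   package version, seed, and per-file MD5 checksums.
#' @return A list: `cohort`, `csf_thresholds`, `trial_logs`,
#'   `csf_summaries`, `sweep_responses`, `vep_fits`, `disparities`,
#'   `report`, and (when written) `manifest`.
#' @export
run_full_study <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(
    config$cohort,
    seed = substream_seed(config$seed, .stage[["cohort"]])
  )
  if (config$eye_mode == "random-one") {
    # emulate one-random-eye-per-subject sampling: eyes are paired in
    # generation order within each group and one of each pair is kept
    cohort <- with_seed(substream_seed(config$seed, .stage[["cohort"]], 2), {
      keep <- cohort |>
        dplyr::mutate(.row = dplyr::row_number()) |>
        dplyr::group_by(.data$group) |>
        dplyr::mutate(.pair = (dplyr::row_number() + 1L) %/% 2L) |>
        dplyr::group_by(.data$group, .data$.pair) |>
        dplyr::slice_sample(n = 1) |>
        dplyr::ungroup()
      cohort[sort(keep$.row), ]
    })
  }
  n_eye <- nrow(cohort)

  csf_thresholds <- vector("list", n_eye)
  trial_logs <- vector("list", n_eye)
  csf_summaries <- vector("list", n_eye)
  sweep_responses <- vector("list", n_eye)
  vep_rows <- vector("list", n_eye)
  for (i in seq_len(n_eye)) {
    obs <- cohort$observer[[i]]
    eye <- cohort$eye_id[i]
    grp <- cohort$group[i]
    csf <- run_eye_csf(obs, config, i)
    csf_thresholds[[i]] <- dplyr::mutate(
      csf$thresholds, eye_id = eye, group = grp
    )
    trial_logs[[i]] <- dplyr::mutate(
      csf$trial_logs, eye_id = eye, group = grp
    )
    csf_summaries[[i]] <- dplyr::mutate(
      csf$summaries, eye_id = eye, group = grp
    )
    svep <- run_eye_svep(obs, config, i)
    sweep_responses[[i]] <- dplyr::mutate(
      dplyr::bind_rows(svep$strong$response, svep$weak$response),
      eye_id = eye, group = grp
    )
    vep_rows[[i]] <- tibble(
      eye_id = eye, group = grp,
      meridian = c("strong", "weak"),
      threshold = c(svep$strong$fit$threshold, svep$weak$fit$threshold),
      valid = c(svep$strong$fit$valid, svep$weak$fit$valid),
      reason = c(svep$strong$fit$reason, svep$weak$fit$reason)
    )
  }
  csf_thresholds <- purrr::list_rbind(csf_thresholds)
  trial_logs <- purrr::list_rbind(trial_logs)
  csf_summaries <- purrr::list_rbind(csf_summaries)
  sweep_responses <- purrr::list_rbind(sweep_responses)
  vep_fits <- purrr::list_rbind(vep_rows)

  disparities <- assemble_disparities(
    csf_summaries, csf_thresholds, sweep_responses, vep_fits
  )
  report <- build_disparity_report(disparities)

  out <- list(
    cohort = cohort, csf_thresholds = csf_thresholds,
    trial_logs = trial_logs, csf_summaries = csf_summaries,
    sweep_responses = sweep_responses, vep_fits = vep_fits,
    disparities = disparities, report = report
  )
  if (!is.null(out_dir)) {
    out$manifest <- write_study_artifacts(out, config, out_dir)
  }
  out
}

# Pivot per-eye, per-meridian results into strong/weak disparity
# records for every metric. sVEP thresholds are excluded pairwise:
# an eye contributes only if both meridians' fits are valid.
assemble_disparities <- function(csf_summaries, csf_thresholds,
                                 sweep_responses, vep_fits) {
  csf_long <- csf_summaries |>
    tidyr::pivot_longer(
      cols = c("aulcsf", "csf_acuity", "sf_threshold_80"),
      names_to = "metric", values_to = "value"
    ) |>
    tidyr::pivot_wider(
      id_cols = c("eye_id", "group", "metric"),
      names_from = "meridian", values_from = "value"
    )
  per_sf <- csf_thresholds |>
    dplyr::filter(.data$converged) |>
    dplyr::mutate(
      value = log10(1 / .data$threshold),
      metric = sprintf("sensitivity_%g_cpd", .data$sf)
    ) |>
    tidyr::pivot_wider(
      id_cols = c("eye_id", "group", "metric"),
      names_from = "meridian", values_from = "value"
    )
  amp <- sweep_responses |>
    dplyr::mutate(metric = sprintf("amplitude_%.1f_cpd", .data$swept_sf)) |>
    tidyr::pivot_wider(
      id_cols = c("eye_id", "group", "metric"),
      names_from = "meridian", values_from = "amplitude"
    )
  both_valid <- vep_fits |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::filter(all(.data$valid)) |>
    dplyr::ungroup()
  vep <- both_valid |>
    dplyr::mutate(metric = "svep_threshold") |>
    tidyr::pivot_wider(
      id_cols = c("eye_id", "group", "metric"),
      names_from = "meridian", values_from = "threshold"
    )
  dplyr::bind_rows(csf_long, per_sf, amp, vep) |>
    dplyr::filter(is.finite(.data$strong), is.finite(.data$weak)) |>
    dplyr::mutate(disparity = .data$strong - .data$weak)
}

write_study_artifacts <- function(out, config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'.", out_dir))
  }
  cohort_flat <- out$cohort |>
    dplyr::select(-"observer")
  tables <- list(
    cohort = cohort_flat,
    trial_logs = out$trial_logs,
    csf_thresholds = out$csf_thresholds,
    csf_summaries = out$csf_summaries,
    # amplitude/phase carry the complex coefficient in CSV form
    sweep_responses = dplyr::select(
      out$sweep_responses, -dplyr::any_of(c("channel", "coefficient"))
    ),
    vep_fits = out$vep_fits,
    disparities = out$disparities,
    disparity_report = as_tibble(out$report)
  )
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], f)
    files <- c(files, f)
  }
  manifest <- list(
    package = "meridianvis",
    version = as.character(utils::packageVersion("meridianvis")),
    seed = config$seed,
    files = lapply(setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA
  )
  manifest
}

#' Parameter-recovery validation of the whole pipeline
#'
#' Re-runs the measurement chains on a cohort whose generative truths
#' are retained, and reports per-eye (generative, estimated) pairs for
#' the CSF summaries and the sVEP thresholds together with recovery
#' error summaries. With the noise turned down the estimates collapse
#' onto the generative values; at the default noise level the recovery
#' errors quantify what the measurement chains add.
#'
#' @param config A [run_config()]; `validate_pipeline()` runs the
#'   study it describes.
#' @return A list with `pairs` (tibble of per-eye generative vs
#'   estimated values per metric and meridian) and `summary` (median
#'   and 90th-percentile absolute errors per metric).
#' @export
validate_pipeline <- function(config = run_config()) {
  study <- run_full_study(config)
  cohort <- study$cohort
  gen_rows <- purrr::pmap(
    list(cohort$eye_id, cohort$group, cohort$observer),
    function(eye, grp, obs) {
      purrr::list_rbind(lapply(c("strong", "weak"), function(m) {
        csf <- if (m == "strong") obs$csf_strong else obs$csf_weak
        grid <- 10^seq(log10(0.25), log10(64), length.out = 400)
        pts <- tibble(
          sf = grid, log10_sf = log10(grid),
          log10_sensitivity = log10(csf_sensitivity(csf, grid))
        )
        acu <- compute_csf_acuity(pts)
        sf80 <- compute_sf_threshold_at_contrast(pts, 0.80)
        tibble(
          eye_id = eye, group = grp, meridian = m,
          metric = c("aulcsf", "csf_acuity", "sf_threshold_80",
            "svep_threshold"),
          generative = c(
            compute_aulcsf(pts), as.numeric(acu), as.numeric(sf80),
            if (m == "strong") obs$vep_threshold_strong else
              obs$vep_threshold_weak
          )
        )
      }))
    }
  )
  generative <- purrr::list_rbind(gen_rows)
  estimated <- dplyr::bind_rows(
    study$csf_summaries |>
      tidyr::pivot_longer(
        cols = c("aulcsf", "csf_acuity", "sf_threshold_80"),
        names_to = "metric", values_to = "estimated"
      ) |>
      dplyr::select("eye_id", "group", "meridian", "metric", "estimated"),
    study$vep_fits |>
      dplyr::mutate(metric = "svep_threshold") |>
      dplyr::select("eye_id", "group", "meridian", "metric",
        estimated = "threshold")
  )
  pairs <- dplyr::left_join(
    generative, estimated,
    by = c("eye_id", "group", "meridian", "metric")
  ) |>
    dplyr::mutate(error = .data$estimated - .data$generative)
  summary <- pairs |>
    dplyr::filter(is.finite(.data$error)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_abs_error = median(abs(.data$error)),
      q90_abs_error = unname(stats::quantile(abs(.data$error), 0.9)),
      .groups = "drop"
    )
  list(pairs = pairs, summary = summary)
}
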