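#' Run the weaning-estimation pipeline on a cohort
#'
#' Applies the full per-series chain to every (specimen, element) transect:
#' half-LOD substitution, single-pass 4-SD outlier removal, registration
#' onto the growth-layer coordinate, restriction to the first five growth
#' layer groups, Savitzky-Golay smoothing, initial-rise trimming, pattern
#' classification and mathematical weaning estimation. A failure in one
#' series (for example a transect too short to smooth) is logged and
#' converted to a `no_signal` estimate; it never aborts the cohort.
#'
#' @param transects Transect tibble ([read_transects()] format).
#' @param layers Layer annotations ([read_layer_annotations()] format).
#' @param config A [weanpoint_config()].
#' @return A list of class `"weaning_pipeline"`: `estimates` (one row per
#'   series), `patterns` (classification diagnostics for estimable series),
#'   `processed` (the cleaned, registered, smoothed, trimmed samples) and
#'   `counts` (per-stage bookkeeping).
#' @export
run_weaning_pipeline <- function(transects, layers,
                                 config = weanpoint_config()) {
  keys <- c("specimen_id", "element")
  if (!all(keys %in% names(transects))) {
    abort("`transects` needs specimen_id and element columns.")
  }
  series_list <- dplyr::group_split(
    dplyr::group_by(transects, dplyr::pick(dplyr::all_of(keys)))
  )
  results <- lapply(series_list, function(d) {
    id <- d$specimen_id[1]; el <- d$element[1]
    tryCatch(
      process_series(d, layers[layers$specimen_id == id, ], config),
      error = function(e) {
        inform(sprintf("Skipping %s/%s: %s", id, el, conditionMessage(e)))
        list(
          estimate = tibble::tibble(
            specimen_id = id, element = el, method = "mathematical",
            status = "no_signal", layer_label = NA_character_,
            layer_ordinal = NA_integer_, psi_ell = NA_real_,
            pattern = NA_character_, fit_method = NA_character_,
            converged = NA, rss = NA_real_,
            reason = conditionMessage(e)
          ),
          pattern = NULL, processed = NULL, counts = NULL
        )
      }
    )
  })
  estimates <- dplyr::bind_rows(lapply(results, `[[`, "estimate"))
  structure(
    list(
      estimates = estimates,
      patterns = dplyr::bind_rows(lapply(results, `[[`, "pattern")),
      processed = dplyr::bind_rows(lapply(results, `[[`, "processed")),
      counts = dplyr::bind_rows(lapply(results, `[[`, "counts"))
    ),
    class = "weaning_pipeline"
  )
}

process_series <- function(d, ann, config) {
  id <- d$specimen_id[1]; el <- d$element[1]
  n_read <- nrow(d)
  d <- substitute_below_lod(d)
  lod_rep <- cleaning_report(d)
  d <- remove_outliers(d, k = config$outlier_k)
  out_rep <- cleaning_report(d)
  d <- suppressMessages(attach_layer_coordinate(d, ann))
  d <- suppressMessages(truncate_to_first_five_glgs(d, config = config))
  d <- savgol_smooth(d, window = config$window, polyorder = config$polyorder)
  d <- trim_initial_rise(d, config)
  trim_rep <- attr(d, "trim_report")
  est <- estimate_one(d$ell, d$conc_ppm, config)
  pat <- if (!is.na(est$pattern[1])) {
    dplyr::bind_cols(tibble::tibble(specimen_id = id, element = el),
                     classify_pattern(d[, c("ell", "conc_ppm")], config))
  }
  list(
    estimate = dplyr::bind_cols(tibble::tibble(specimen_id = id, element = el), est),
    pattern = pat,
    processed = d,
    counts = tibble::tibble(
      specimen_id = id, element = el,
      n_read = n_read,
      n_below_lod = lod_rep$n_below_lod[1],
      n_outliers_removed = out_rep$n_outliers_removed[1],
      n_analyzed = nrow(d),
      trimmed_n = trim_rep$trimmed_n[1]
    )
  )
}

#' @export
print.weaning_pipeline <- function(x, ...) {
  cat("<weaning_pipeline>\n")
  cat(sprintf("  %d series; %d estimated, %d no_signal\n",
              nrow(x$estimates),
              sum(x$estimates$status == "estimated"),
              sum(x$estimates$status == "no_signal")))
  invisible(x)
}

#' @method glance weaning_pipeline
#' @export
glance.weaning_pipeline <- function(x, ...) {
  tibble::tibble(
    n_series = nrow(x$estimates),
    n_estimated = sum(x$estimates$status == "estimated"),
    n_no_signal = sum(x$estimates$status == "no_signal")
  )
}

#' Run the full pipeline from files or a fresh simulation
#'
#' Orchestrates `simulate -> preprocess -> estimate -> classify ->
#' summarize` in one call. Inputs come either from a directory holding
#' `transects.csv`, `layers.csv` and optionally `meta.csv` / `visual.csv`,
#' or from the synthetic generator when `n` is given. All outputs
#' (intermediate tables, estimates, summary and a provenance record with the
#' configuration snapshot and per-stage counts) are written under
#' `out_dir`.
#'
#' @param out_dir Output directory.
#' @param in_dir Input directory; ignored when `n` is given.
#' @param n If non-NULL, simulate a cohort of this size instead of reading
#'   inputs.
#' @param seed Seed for simulation.
#' @param config A [weanpoint_config()].
#' @param params A [generator_params()] for simulation.
#' @return The [summarize_cohort()] result, invisibly, with the pipeline
#'   result attached as attribute `"pipeline"`.
#' @export
run_all <- function(out_dir, in_dir = NULL, n = NULL, seed = 1L,
                    config = weanpoint_config(),
                    params = generator_params()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(n)) {
    cohort <- simulate_cohort(n, params, seed)
    write_cohort(cohort, file.path(out_dir, "inputs"))
    transects <- cohort$transects
    layers <- cohort$layers
    meta <- cohort$meta
    visual <- import_visual_estimates(cohort$visual)
  } else {
    if (is.null(in_dir) || !dir.exists(in_dir)) {
      abort("Provide `n` to simulate or an existing `in_dir` to read.")
    }
    transects <- suppressWarnings(
      read_transects(file.path(in_dir, "transects.csv"), config)
    )
    layers <- read_layer_annotations(file.path(in_dir, "layers.csv"))
    meta_path <- file.path(in_dir, "meta.csv")
    meta <- if (file.exists(meta_path)) read_specimen_meta(meta_path)
    visual_path <- file.path(in_dir, "visual.csv")
    visual <- if (file.exists(visual_path)) read_visual_estimates(visual_path)
  }

  pipe <- run_weaning_pipeline(transects, layers, config)
  write_weaning_estimates(pipe$estimates, file.path(out_dir, "estimates.csv"))
  if (nrow(pipe$patterns)) {
    readr::write_csv(pipe$patterns, file.path(out_dir, "patterns.csv"), na = "")
  }
  summary <- summarize_cohort(pipe$estimates, visual = visual, meta = meta)
  jsonlite::write_json(
    unclass(summary), file.path(out_dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  provenance <- list(
    package_version = as.character(utils::packageVersion("weanpoint")),
    config = unclass(config),
    seed = seed,
    simulated = !is.null(n),
    counts = pipe$counts,
    n_estimated = sum(pipe$estimates$status == "estimated"),
    n_no_signal = sum(pipe$estimates$status == "no_signal"),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(
    provenance, file.path(out_dir, "provenance.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  attr(summary, "pipeline") <- pipe
  invisible(summary)
}
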