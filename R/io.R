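#' Read laser-ablation transect tables
#'
#' Reads a delimited table of element concentrations sampled along ablation
#' transects, one row per sample, and validates it into the package's
#' canonical long format. Each (specimen, element) pair is one transect
#' series. Distance along the transect is the canonical coordinate; rows
#' carrying only acquisition time are converted using the laser scan speed.
#'
#' @param path CSV file with header columns `specimen_id`, `element`,
#'   `conc_ppm`, and at least one of `time_s` / `distance_um`; optional
#'   `lod_ppm` and `run_id`.
#' @param config A [weanpoint_config()]; supplies the scan speed and default
#'   detection limits.
#'
#' @return A tibble with columns `specimen_id`, `element`, `time_s`,
#'   `distance_um`, `conc_ppm`, `lod_ppm`, `run_id`, sorted by distance
#'   within each series. Rows with missing `conc_ppm` are dropped with a
#'   message. Detection limits absent from the file are filled with the
#'   configured typical values (0.18 ppm Sr, 0.34 ppm Ba) with a warning.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "specimen_id,element,time_s,conc_ppm",
#'   "W-001,Sr88,0,400", "W-001,Sr88,1,390", "W-001,Sr88,2,380"
#' ), path)
#' suppressWarnings(read_transects(path))
#' @export
read_transects <- function(path, config = weanpoint_config()) {
  df <- read_table_checked(path, required = c("specimen_id", "element", "conc_ppm"))
  if (!any(c("time_s", "distance_um") %in% names(df))) {
    abort(sprintf(
      "%s: need a 'time_s' and/or 'distance_um' column.", path
    ))
  }
  if (!"time_s" %in% names(df)) df$time_s <- NA_real_
  if (!"distance_um" %in% names(df)) df$distance_um <- NA_real_
  if (!"lod_ppm" %in% names(df)) df$lod_ppm <- NA_real_
  if (!"run_id" %in% names(df)) df$run_id <- NA_character_

  df <- dplyr::mutate(
    df,
    dplyr::across(c("time_s", "distance_um", "conc_ppm", "lod_ppm"), as.numeric),
    specimen_id = as.character(.data$specimen_id),
    element = as.character(.data$element),
    run_id = as.character(.data$run_id)
  )

  n_missing <- sum(is.na(df$conc_ppm))
  if (n_missing > 0) {
    inform(sprintf("Dropping %d row(s) with missing conc_ppm.", n_missing))
    df <- dplyr::filter(df, !is.na(.data$conc_ppm))
  }
  if (any(!is.finite(df$conc_ppm))) {
    abort(sprintf("%s: non-finite conc_ppm values present.", path))
  }

  speed <- config$scan_speed_um_s
  no_dist <- is.na(df$distance_um)
  if (any(no_dist & is.na(df$time_s))) {
    abort(sprintf("%s: rows with neither time_s nor distance_um.", path))
  }
  df$distance_um[no_dist] <- df$time_s[no_dist] * speed

  both <- !is.na(df$time_s) & !no_dist
  if (any(both)) {
    expected <- df$time_s[both] * speed
    scale <- pmax(abs(expected), 1)
    bad <- abs(df$distance_um[both] - expected) > 1e-6 * scale
    if (any(bad)) {
      abort(sprintf(
        "%s: distance_um inconsistent with time_s x scan speed (%g um/s) at %d row(s), e.g. row %d.",
        path, speed, sum(bad), which(both)[which(bad)[1]]
      ))
    }
  }

  if (any(df$distance_um < 0, na.rm = TRUE) || any(df$time_s < 0, na.rm = TRUE)) {
    abort(sprintf("%s: negative time or distance.", path))
  }

  df <- dplyr::arrange(df, .data$specimen_id, .data$element, .data$distance_um)
  bad_series <- df |>
    dplyr::summarise(
      non_mono = any(diff(.data$distance_um) <= 0),
      .by = c("specimen_id", "element")
    ) |>
    dplyr::filter(.data$non_mono)
  if (nrow(bad_series) > 0) {
    rows <- df |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::filter(
        .data$specimen_id %in% bad_series$specimen_id,
        c(FALSE, diff(.data$distance_um) <= 0)
      )
    abort(sprintf(
      "%s: distance_um not strictly increasing within series %s (e.g. sorted row %s).",
      path,
      paste(unique(bad_series$specimen_id), collapse = ", "),
      paste(utils::head(rows$.row, 3), collapse = ", ")
    ))
  }

  fill <- is.na(df$lod_ppm)
  if (any(fill)) {
    df$lod_ppm[fill] <- default_lod(df$element[fill], config)
    warn(sprintf(
      "%d row(s) had no lod_ppm; using typical detection limits (Sr %.2f, Ba %.2f ppm).",
      sum(fill), config$lod_sr_ppm, config$lod_ba_ppm
    ))
  }
  if (any(is.na(df$lod_ppm) | df$lod_ppm <= 0)) {
    abort(sprintf("%s: missing or non-positive lod_ppm for an element without a configured default.", path))
  }
  tibble::as_tibble(df)
}

#' Read growth-layer annotations
#'
#' Reads per-specimen growth-layer intervals along the transect. Layers must
#' tile the annotated span contiguously (each layer ends where the next
#' starts) and alternate light/dark starting at `L1`, the first light layer.
#'
#' @param path CSV file with columns `specimen_id`, `layer_label`,
#'   `start_um`, `end_um`.
#' @return A tibble sorted by `start_um` within specimen, with an added
#'   integer `ordinal` column (`L1` = 1, `D1` = 2, ...).
#' @export
read_layer_annotations <- function(path) {
  df <- read_table_checked(
    path, required = c("specimen_id", "layer_label", "start_um", "end_um")
  )
  df <- dplyr::mutate(
    df,
    specimen_id = as.character(.data$specimen_id),
    layer_label = as.character(.data$layer_label),
    dplyr::across(c("start_um", "end_um"), as.numeric)
  )
  df$ordinal <- layer_ordinal(df$layer_label)
  df <- dplyr::arrange(df, .data$specimen_id, .data$start_um)
  validate_layer_annotations(df, context = path)
  tibble::as_tibble(df)
}

validate_layer_annotations <- function(df, context = "layer annotations") {
  if (any(df$start_um >= df$end_um)) {
    abort(sprintf("%s: layer with start_um >= end_um.", context))
  }
  per <- split(df, df$specimen_id)
  for (specimen in names(per)) {
    ann <- per[[specimen]]
    if (!identical(ann$ordinal, seq_len(nrow(ann)))) {
      abort(sprintf(
        "%s: specimen %s layers must alternate light/dark from L1 (expected %s, got %s).",
        context, specimen,
        paste(layer_label(seq_len(nrow(ann))), collapse = ","),
        paste(ann$layer_label, collapse = ",")
      ))
    }
    if (nrow(ann) > 1) {
      gaps <- abs(ann$end_um[-nrow(ann)] - ann$start_um[-1])
      tol <- 1e-9 * pmax(abs(ann$end_um[-nrow(ann)]), 1)
      if (any(gaps > tol)) {
        i <- which(gaps > tol)[1]
        abort(sprintf(
          "%s: specimen %s has a gap/overlap between %s (end %g) and %s (start %g).",
          context, specimen, ann$layer_label[i], ann$end_um[i],
          ann$layer_label[i + 1], ann$start_um[i + 1]
        ))
      }
    }
  }
  invisible(df)
}

#' Read specimen metadata
#'
#' @param path CSV file with columns `specimen_id`, `sex` (`F`, `M` or
#'   `unknown`), `collection_year`, `estimated_age_years`.
#' @return A tibble with a derived `birth_year` column
#'   (`collection_year - round(estimated_age_years)`).
#' @export
read_specimen_meta <- function(path) {
  df <- read_table_checked(
    path, required = c("specimen_id", "sex", "collection_year", "estimated_age_years")
  )
  df <- dplyr::mutate(
    df,
    specimen_id = as.character(.data$specimen_id),
    sex = as.character(.data$sex),
    collection_year = as.integer(.data$collection_year),
    estimated_age_years = as.numeric(.data$estimated_age_years)
  )
  bad_sex <- !df$sex %in% c("F", "M", "unknown")
  if (any(bad_sex)) {
    abort(sprintf("%s: sex must be one of F, M, unknown (got %s).",
                  path, paste(unique(df$sex[bad_sex]), collapse = ", ")))
  }
  if (any(df$estimated_age_years < 0, na.rm = TRUE)) {
    abort(sprintf("%s: negative estimated_age_years.", path))
  }
  df$birth_year <- df$collection_year - as.integer(round(df$estimated_age_years))
  tibble::as_tibble(df)
}

#' Read visual weaning estimates
#'
#' Imports human visual assignments of the weaning signal to a growth layer.
#' A missing `layer_label` denotes an animal for which no weaning signal
#' could be identified.
#'
#' @param path CSV file with columns `specimen_id`, `element`, `layer_label`
#'   (may be empty/NA).
#' @return A tibble of weaning estimates with `method = "visual"`; see
#'   [import_visual_estimates()].
#' @export
read_visual_estimates <- function(path) {
  df <- read_table_checked(path, required = c("specimen_id", "element", "layer_label"))
  import_visual_estimates(df)
}

#' Write and re-read weaning estimates
#'
#' `write_weaning_estimates()` serializes per-animal weaning estimates to
#' CSV; `read_weaning_estimates()` reads them back field-for-field, so the
#' pair round-trips exactly.
#'
#' @param estimates A non-empty tibble of weaning estimates with columns
#'   `specimen_id`, `element`, `method`, `status`, `layer_label`,
#'   `layer_ordinal`, `psi_ell`.
#' @param path Output/input CSV path.
#' @return `write_weaning_estimates()` returns `path` invisibly;
#'   `read_weaning_estimates()` returns the estimates tibble.
#' @export
write_weaning_estimates <- function(estimates, path) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0) {
    abort("Refusing to write an empty estimates table.")
  }
  cols <- c("specimen_id", "element", "method", "status",
            "layer_label", "layer_ordinal", "psi_ell")
  missing <- setdiff(cols, names(estimates))
  if (length(missing)) {
    abort(sprintf("Estimates table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(estimates[cols], path, na = "")
  invisible(path)
}

#' @rdname write_weaning_estimates
#' @export
read_weaning_estimates <- function(path) {
  df <- read_table_checked(
    path,
    required = c("specimen_id", "element", "method", "status",
                 "layer_label", "layer_ordinal", "psi_ell")
  )
  tibble::tibble(
    specimen_id = as.character(df$specimen_id),
    element = as.character(df$element),
    method = as.character(df$method),
    status = as.character(df$status),
    layer_label = dplyr::if_else(is.na(df$layer_label) | df$layer_label == "",
                                 NA_character_, as.character(df$layer_label)),
    layer_ordinal = as.integer(df$layer_ordinal),
    psi_ell = as.numeric(df$psi_ell)
  )
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  df
}
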