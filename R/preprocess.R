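#' Substitute concentrations below the detection limit
#'
#' Element concentrations falling strictly below the limit of detection
#' (LOD) are left-censored observations; the standard simple treatment
#' replaces each with half the detection limit. Values exactly equal to the
#' LOD are detectable and left unchanged.
#'
#' @param data A transect tibble with a `conc_ppm` column; if `specimen_id`
#'   and/or `element` columns are present each series is treated separately.
#' @param lod Detection limit in ppm (> 0). If `NULL`, the per-row `lod_ppm`
#'   column is used.
#' @return The tibble with censored values replaced by `lod / 2`. A
#'   per-series cleaning report is attached as attribute
#'   `"cleaning_report"` (see [cleaning_report()]) with columns
#'   `n_below_lod` and `lod_used`.
#' @examples
#' x <- tibble::tibble(conc_ppm = c(0.10, 0.50, 0.20))
#' substitute_below_lod(x, lod = 0.34)
#' @seealso [remove_outliers()], [savgol_smooth()]
#' @export
substitute_below_lod <- function(data, lod = NULL) {
  check_conc(data)
  if (!is.null(lod)) {
    if (!is.numeric(lod) || length(lod) != 1 || is.na(lod) || lod <= 0) {
      abort("`lod` must be a single positive number (ppm).")
    }
    lod_vec <- rep(lod, nrow(data))
  } else {
    if (!"lod_ppm" %in% names(data)) {
      abort("No `lod` given and no `lod_ppm` column present.")
    }
    lod_vec <- data$lod_ppm
    if (any(is.na(lod_vec) | lod_vec <= 0)) {
      abort("`lod_ppm` column contains missing or non-positive values.")
    }
  }
  below <- data$conc_ppm < lod_vec
  out <- data
  out$conc_ppm[below] <- lod_vec[below] / 2
  report <- series_summarise(
    dplyr::mutate(out, .below = below, .lod = lod_vec),
    function(d) tibble::tibble(
      n_below_lod = sum(d$.below),
      lod_used = d$.lod[1]
    )
  )
  out$.below <- NULL
  attr(out, "cleaning_report") <- report
  out
}

#' Remove extreme outlier samples
#'
#' Samples more than `k` standard deviations above or below the series mean
#' are treated as measurement artifacts and removed. The mean and SD are
#' computed once over the full series (single pass, no re-iteration), so the
#' rule cannot cascade through the transect; typical hits are single spikes.
#' A constant series (SD = 0) yields no removals.
#'
#' @inheritParams substitute_below_lod
#' @param k SD multiplier (> 0); default 4.
#' @return The tibble with outlier rows removed; the attached
#'   `"cleaning_report"` lists `n_outliers_removed`, the within-series
#'   `outlier_indices` (list column) and `k_used`. Each series must have at
#'   least 3 samples.
#' @examples
#' x <- tibble::tibble(conc_ppm = c(rep(10, 100), 20))
#' nrow(remove_outliers(x, k = 4))
#' @export
remove_outliers <- function(data, k = 4) {
  check_conc(data)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k <= 0) {
    abort("`k` must be a single positive number.")
  }
  keys <- series_keys(data)
  grouped <- if (length(keys)) dplyr::group_by(data, dplyr::pick(dplyr::all_of(keys))) else
    dplyr::group_by(data, .dummy = rep(1L, nrow(data)))
  sizes <- dplyr::group_size(grouped)
  if (any(sizes < 3)) {
    abort("Outlier removal needs at least 3 samples per series.")
  }
  flagged <- dplyr::mutate(grouped, .out = {
    m <- mean(.data$conc_ppm)
    s <- sd(.data$conc_ppm)
    if (s == 0) rep(FALSE, dplyr::n()) else abs(.data$conc_ppm - m) > k * s
  })
  report <- dplyr::summarise(
    flagged,
    n_outliers_removed = sum(.data$.out),
    outlier_indices = list(which(.data$.out)),
    k_used = k,
    .groups = "drop"
  )
  out <- dplyr::ungroup(dplyr::filter(flagged, !.data$.out))
  out$.out <- NULL
  out$.dummy <- NULL
  report$.dummy <- NULL
  attr(out, "cleaning_report") <- tibble::as_tibble(report)
  out
}

#' Savitzky-Golay smoothing
#'
#' Applies a centred Savitzky-Golay filter: each interior point is replaced
#' by the value at the centre of a local least-squares polynomial fit over
#' `window` consecutive samples. The filter is phase-preserving (no
#' left/right shift) and reproduces polynomials up to `polyorder` exactly.
#' Edges are truncated rather than padded: the output loses
#' `(window - 1) / 2` points at each end of every series.
#'
#' @inheritParams substitute_below_lod
#' @param window Odd window length in samples (default 15).
#' @param polyorder Polynomial order (default 3; must be `< window`).
#' @return The tibble restricted to interior points, with `conc_ppm`
#'   replaced by its smoothed value. Any series shorter than `window` is an
#'   error: short series cannot be smoothed and should be flagged upstream.
#' @examples
#' x <- tibble::tibble(conc_ppm = seq(0, 3, length.out = 31)^3)
#' sm <- savgol_smooth(x, window = 15, polyorder = 3)
#' nrow(sm)  # 31 - 2 * 7
#' @export
savgol_smooth <- function(data, window = 15, polyorder = 3) {
  check_conc(data)
  if (window %% 2 != 1 || window < 3) abort("`window` must be an odd integer >= 3.")
  if (polyorder >= window) abort("`polyorder` must be smaller than `window`.")
  half <- (window - 1) / 2
  weights <- sg_center_weights(window, polyorder)
  keys <- series_keys(data)
  smooth_one <- function(d, ...) {
    n <- nrow(d)
    if (n < window) {
      abort(sprintf(
        "Series of %d points is shorter than the %d-point smoothing window; flag it as a short series instead of smoothing.",
        n, window
      ))
    }
    sm <- as.numeric(stats::filter(d$conc_ppm, weights, sides = 2))
    keep <- (half + 1):(n - half)
    d <- d[keep, , drop = FALSE]
    d$conc_ppm <- sm[keep]
    d
  }
  if (length(keys)) {
    out <- data |>
      dplyr::group_by(dplyr::pick(dplyr::all_of(keys))) |>
      dplyr::group_modify(smooth_one) |>
      dplyr::ungroup()
    out <- out[, names(data), drop = FALSE]
  } else {
    out <- smooth_one(data)
  }
  tibble::as_tibble(out)
}

# Centre row of the Savitzky-Golay projection: value of the local
# least-squares polynomial at the window midpoint. Symmetric, so it can be
# used directly as a convolution kernel with stats::filter(sides = 2).
sg_center_weights <- function(window, polyorder) {
  S <- signal::sgolay(p = polyorder, n = window)
  as.numeric(S[(window + 1) / 2, ])
}

#' Retrieve the cleaning report attached by a preprocessing step
#'
#' @param data A tibble returned by [substitute_below_lod()] or
#'   [remove_outliers()].
#' @return The per-series report tibble, or `NULL` if none is attached.
#' @export
cleaning_report <- function(data) {
  attr(data, "cleaning_report", exact = TRUE)
}

check_conc <- function(data) {
  if (!is.data.frame(data) || !"conc_ppm" %in% names(data)) {
    abort("`data` must be a data frame with a `conc_ppm` column.")
  }
  if (any(is.na(data$conc_ppm))) {
    abort("`conc_ppm` contains missing values; drop or impute them first.")
  }
  invisible(data)
}

series_keys <- function(data) {
  intersect(c("specimen_id", "element"), names(data))
}

series_summarise <- function(data, f) {
  keys <- series_keys(data)
  if (length(keys)) {
    data |>
      dplyr::group_by(dplyr::pick(dplyr::all_of(keys))) |>
      dplyr::group_modify(function(d, ...) f(d)) |>
      dplyr::ungroup()
  } else {
    f(data)
  }
}
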