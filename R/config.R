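#' Run configuration
#'
#' All tunables of the pipeline in one validated list. `weanpoint_config()`
#' builds a configuration from defaults plus overrides; `load_config()` reads
#' overrides from a JSON file. Unknown keys are an error (they are almost
#' always typos), as are out-of-range values.
#'
#' Defaults follow the acquisition and processing settings of the walrus
#' cementum study design this package implements: a 15-point Savitzky-Golay
#' window, a 4-standard-deviation outlier rule, typical detection limits of
#' 0.18 ppm (Sr) and 0.34 ppm (Ba), and a 5 um/s laser scan speed.
#'
#' @param ... Named overrides of the defaults listed below.
#' @param path Path to a JSON file whose top-level object holds overrides.
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{`window` (15)}{Savitzky-Golay window length in samples; odd.}
#'   \item{`polyorder` (3)}{Savitzky-Golay polynomial order; `< window`.}
#'   \item{`outlier_k` (4)}{SD multiplier for the outlier rule.}
#'   \item{`lod_sr_ppm` (0.18), `lod_ba_ppm` (0.34)}{Default detection limits
#'     used when a transect carries none.}
#'   \item{`scan_speed_um_s` (5)}{Laser scan speed; converts time to distance.}
#'   \item{`min_seg` (5)}{Minimum points per segment in breakpoint fits.}
#'   \item{`min_seg_frac` (0.05)}{Classification and weaning estimation use
#'     `max(min_seg, ceiling(min_seg_frac * n))` points per segment, so that
#'     densely sampled transects (1 um spacing gives ~1,700 points over five
#'     GLGs) cannot place a breakpoint a few micrometres from the series
#'     boundary.}
#'   \item{`grid_size` (80)}{Per-axis grid resolution for the 2-breakpoint
#'     grid search; the 1-breakpoint grid is always exhaustive over observed
#'     interior abscissa values.}
#'   \item{`tol` (1e-8)}{Convergence tolerance of the iterative breakpoint
#'     update, relative to the abscissa range.}
#'   \item{`max_iter` (50)}{Iteration cap for the iterative fitter.}
#'   \item{`flat_frac` (0.1)}{Flatness threshold for pattern rules, as a
#'     fraction of the concentration IQR per unit layer coordinate.}
#'   \item{`decline_frac` (0.25)}{Minimum first-to-last-decile decline, as a
#'     fraction of the IQR, below which a profile carries no weaning signal.}
#'   \item{`decile` (0.1)}{Fraction of points in the head/tail windows used
#'     for the decline statistic.}
#'   \item{`trim_ell_max` (2)}{Initial-rise trimming searches for the
#'     concentration maximum over `ell < trim_ell_max` (the first GLG).}
#'   \item{`seed` (NULL)}{Optional default seed for simulation helpers.}
#' }
#'
#' @return A named list of class `"weanpoint_config"`.
#' @examples
#' cfg <- weanpoint_config()
#' cfg$window
#' weanpoint_config(outlier_k = 3)$outlier_k
#' @export
weanpoint_config <- function(...) {
  defaults <- list(
    window = 15L,
    polyorder = 3L,
    outlier_k = 4,
    lod_sr_ppm = 0.18,
    lod_ba_ppm = 0.34,
    scan_speed_um_s = 5,
    min_seg = 5L,
    min_seg_frac = 0.05,
    classify_max_points = 120L,
    grid_size = 80L,
    tol = 1e-8,
    max_iter = 50L,
    flat_frac = 0.1,
    decline_frac = 0.25,
    decile = 0.1,
    trim_ell_max = 2,
    seed = NULL
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("All configuration overrides must be named.")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      abort(sprintf(
        "Unknown configuration key(s): %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  validate_config(cfg)
  structure(cfg, class = "weanpoint_config")
}

validate_config <- function(cfg) {
  stopifnot_scalar <- function(key, test, msg) {
    x <- cfg[[key]]
    if (is.null(x) || length(x) != 1 || is.na(x) || !test(x)) {
      abort(sprintf("Configuration key '%s' %s (got %s).", key, msg,
                    deparse(cfg[[key]])))
    }
  }
  stopifnot_scalar("window", function(x) x >= 3 && x %% 2 == 1,
                   "must be an odd integer >= 3")
  stopifnot_scalar("polyorder", function(x) x >= 0 && x < cfg$window,
                   "must be a non-negative integer smaller than the window")
  stopifnot_scalar("outlier_k", function(x) x > 0, "must be > 0")
  stopifnot_scalar("lod_sr_ppm", function(x) x > 0, "must be > 0")
  stopifnot_scalar("lod_ba_ppm", function(x) x > 0, "must be > 0")
  stopifnot_scalar("scan_speed_um_s", function(x) x > 0, "must be > 0")
  stopifnot_scalar("min_seg", function(x) x >= 2, "must be an integer >= 2")
  stopifnot_scalar("min_seg_frac", function(x) x >= 0 && x < 0.5,
                   "must be in [0, 0.5)")
  stopifnot_scalar("classify_max_points", function(x) x >= 30,
                   "must be an integer >= 30")
  stopifnot_scalar("grid_size", function(x) x >= 3, "must be an integer >= 3")
  stopifnot_scalar("tol", function(x) x > 0, "must be > 0")
  stopifnot_scalar("max_iter", function(x) x >= 1, "must be >= 1")
  stopifnot_scalar("flat_frac", function(x) x > 0, "must be > 0")
  stopifnot_scalar("decline_frac", function(x) x >= 0, "must be >= 0")
  stopifnot_scalar("decile", function(x) x > 0 && x <= 0.5,
                   "must be in (0, 0.5]")
  stopifnot_scalar("trim_ell_max", function(x) x > 0 && x <= 10,
                   "must be in (0, 10]")
  invisible(cfg)
}

#' @rdname weanpoint_config
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(weanpoint_config())
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) abort("Config file must hold a JSON object of key: value pairs.")
  int_keys <- c("window", "polyorder", "min_seg", "grid_size", "max_iter",
                "classify_max_points", "seed")
  raw[intersect(names(raw), int_keys)] <-
    lapply(raw[intersect(names(raw), int_keys)], as.integer)
  do.call(weanpoint_config, raw)
}

#' @export
print.weanpoint_config <- function(x, ...) {
  cat("<weanpoint_config>\n")
  for (key in names(x)) {
    cat(sprintf("  %-16s %s\n", key,
                if (is.null(x[[key]])) "NULL" else format(x[[key]])))
  }
  invisible(x)
}

default_lod <- function(element, cfg = weanpoint_config()) {
  dplyr::case_match(
    element,
    "Sr88" ~ cfg$lod_sr_ppm,
    "Ba137" ~ cfg$lod_ba_ppm,
    .default = NA_real_
  )
}
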