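#' Trim initial rising or stable segments
#'
#' Cementum starts accreting a few months after birth, so a nursing-onset
#' signal is not expected; nevertheless some animals show rising or flat
#' concentrations at the very start of the record, which interfere with a
#' single-change-point fit of the weaning decline. This step locates the
#' maximum of the (smoothed) concentration within the first growth layer
#' group (`ell < trim_ell_max`, default the first year of life) and drops
#' all points strictly before it; ties resolve to the earliest point, so a
#' flat or declining series is left untouched.
#'
#' @param data Registered, smoothed tibble with `ell` and `conc_ppm`
#'   columns; series are the distinct (`specimen_id`, `element`) pairs.
#' @param config A [weanpoint_config()] (supplies `trim_ell_max`).
#' @return The trimmed tibble; attribute `"trim_report"` holds per-series
#'   `trimmed_n` counts.
#' @export
trim_initial_rise <- function(data, config = weanpoint_config()) {
  if (!all(c("ell", "conc_ppm") %in% names(data))) {
    abort("`data` needs `ell` and `conc_ppm` columns.")
  }
  trim_one <- function(d) {
    d <- d[order(d$ell), , drop = FALSE]
    window <- which(d$ell < config$trim_ell_max)
    start <- if (length(window)) window[which.max(d$conc_ppm[window])] else 1L
    list(data = d[seq(start, nrow(d)), , drop = FALSE], trimmed_n = start - 1L)
  }
  keys <- series_keys(data)
  if (length(keys)) {
    parts <- dplyr::group_split(dplyr::group_by(data, dplyr::pick(dplyr::all_of(keys))))
    trimmed <- lapply(parts, trim_one)
    out <- dplyr::bind_rows(lapply(trimmed, `[[`, "data"))
    report <- dplyr::bind_cols(
      dplyr::distinct(dplyr::bind_rows(lapply(parts, function(d) d[1, keys, drop = FALSE]))),
      tibble::tibble(trimmed_n = vapply(trimmed, `[[`, integer(1), "trimmed_n"))
    )
  } else {
    tr <- trim_one(data)
    out <- tr$data
    report <- tibble::tibble(trimmed_n = tr$trimmed_n)
  }
  out <- tibble::as_tibble(out)
  attr(out, "trim_report") <- tibble::as_tibble(report)
  out
}

#' Classify the element-accumulation pattern of a series
#'
#' Early-life Sr and Ba profiles fall into four recurring patterns:
#'
#' * **P1** — steep decline to a change point, then a shallower decline to a
#'   second change point, then low and stable;
#' * **P2** — steep decline to a single change point, then consistently low;
#' * **P3** — gentle linear or curvilinear decline with no clear change
#'   point;
#' * **P4** — no early-life decline; the weaning-typical signal is absent.
#'
#' The decision rules quantify these descriptions. With `D` the difference
#' between the mean of the first and last `decile` of points, `S` the IQR of
#' the concentrations, and `tau = flat_frac * S / span(ell)` the flatness
#' threshold: a profile is P4 when `D < decline_frac * S` or its overall OLS
#' slope is non-negative; otherwise the BIC-selected 0/1/2-breakpoint grid
#' fit decides — P1 needs the 2-breakpoint model with increasingly shallow
#' negative slopes and a flat final segment, P2 the 1-breakpoint model with
#' a negative then flat slope, and anything else is P3.
#'
#' @param data Trimmed, smoothed, registered tibble (`ell`, `conc_ppm`).
#' @param config A [weanpoint_config()].
#' @return One row per series: `pattern` (`"P1"`..`"P4"`) plus diagnostics
#'   (`n_bp`, segment slopes, `decline`, `spread`, `tau`).
#' @export
classify_pattern <- function(data, config = weanpoint_config()) {
  per_series_apply(data, function(d) {
    cls <- classify_one(d$ell, d$conc_ppm, config)
    tibble::tibble(
      pattern = cls$pattern,
      n_bp = cls$n_bp,
      slope1 = cls$slopes[1],
      slope2 = if (length(cls$slopes) >= 2) cls$slopes[2] else NA_real_,
      slope3 = if (length(cls$slopes) >= 3) cls$slopes[3] else NA_real_,
      decline = cls$decline,
      spread = cls$spread,
      tau = cls$tau
    )
  })
}

refit_full <- function(n_bp, ell, conc, config) {
  if (n_bp == 0) return(fit_line(ell, conc))
  fit_segmented_grid(ell, conc, n_bp = n_bp,
                     min_seg = effective_min_seg(length(ell), config),
                     grid_size = if (n_bp == 1) Inf else config$grid_size)
}

effective_min_seg <- function(n, config) {
  max(config$min_seg, ceiling(config$min_seg_frac * n))
}

classify_one <- function(ell, conc, config = weanpoint_config()) {
  n <- length(ell)
  ord <- order(ell)
  ell <- ell[ord]; conc <- conc[ord]
  dec_n <- max(1L, floor(config$decile * n))
  decline <- mean(conc[seq_len(dec_n)]) - mean(conc[seq(n - dec_n + 1, n)])
  spread <- IQR(conc)
  span <- diff(range(ell))
  tau <- config$flat_frac * spread / max(span, .Machine$double.eps)

  line <- if (length(unique(ell)) >= 2) fit_line(ell, conc) else NULL
  overall_slope <- if (is.null(line)) 0 else line$slopes[1]

  if (decline < config$decline_frac * spread || overall_slope >= 0) {
    return(list(pattern = "P4", n_bp = NA_integer_,
                slopes = overall_slope, decline = decline,
                spread = spread, tau = tau, fit = line))
  }

  # model selection runs on at most classify_max_points evenly spaced
  # samples: smoothed neighbours are correlated across the filter window,
  # so BIC over every sample would badly overstate the evidence for extra
  # breakpoints
  stride <- ceiling(n / config$classify_max_points)
  sub <- seq(1, n, by = stride)
  best <- select_breakpoint_model(ell[sub], conc[sub], max_bp = 2,
                                  min_seg = effective_min_seg(length(sub), config),
                                  grid_size = config$grid_size)
  # the selected breakpoint count is then refit on the full series: slope
  # rules below compare segment slopes against tau, and the full-data fit
  # has far lower slope variance than the selection subsample
  best <- refit_full(best$n_breakpoints, ell, conc, config)
  s <- best$slopes
  pattern <- if (best$n_breakpoints == 2 &&
                 s[1] < s[2] && s[2] < 0 && abs(s[3]) <= tau) {
    "P1"
  } else if (best$n_breakpoints == 1 && s[1] < 0 && abs(s[2]) <= tau) {
    "P2"
  } else {
    "P3"
  }
  list(pattern = pattern, n_bp = best$n_breakpoints, slopes = s,
       decline = decline, spread = spread, tau = tau, fit = best)
}

#' Estimate the weaning layer mathematically
#'
#' Fits a single change point to each trimmed, smoothed series — the point
#' where the early-life decline in Sr or Ba transitions to stable adult
#' values, i.e. the end of the weaning process — and assigns it to a growth
#' layer. Series classified P4 (no weaning-typical decline) and series too
#' short to fit receive `no_signal` status instead of an estimate. The
#' breakpoint is fit with the iterative algorithm and falls back to the
#' exhaustive grid search when the iteration does not converge.
#'
#' @inheritParams classify_pattern
#' @return A tibble of weaning estimates: `specimen_id`, `element`,
#'   `method = "mathematical"`, `status` (`"estimated"`/`"no_signal"`),
#'   `layer_label`, `layer_ordinal`, `psi_ell`, plus diagnostics
#'   (`pattern`, `fit_method`, `converged`, `rss`, `reason` for missing
#'   estimates).
#' @export
estimate_weaning <- function(data, config = weanpoint_config()) {
  per_series_apply(data, function(d) {
    estimate_one(d$ell, d$conc_ppm, config)
  })
}

estimate_one <- function(ell, conc, config = weanpoint_config()) {
  no_signal <- function(pattern, reason) tibble::tibble(
    method = "mathematical", status = "no_signal",
    layer_label = NA_character_, layer_ordinal = NA_integer_,
    psi_ell = NA_real_, pattern = pattern,
    fit_method = NA_character_, converged = NA, rss = NA_real_,
    reason = reason
  )
  n_needed <- 2 * config$min_seg + 1
  if (length(ell) < n_needed) {
    return(no_signal(NA_character_,
                     sprintf("short series: %d < %d points", length(ell), n_needed)))
  }
  cls <- classify_one(ell, conc, config)
  if (cls$pattern == "P4") {
    return(no_signal("P4", "no weaning-typical decline"))
  }
  min_seg <- effective_min_seg(length(ell), config)
  fit <- fit_segmented_iterative(ell, conc, n_bp = 1, tol = config$tol,
                                 max_iter = config$max_iter,
                                 min_seg = min_seg)
  if (!fit$converged) {
    fit <- fit_segmented_grid(ell, conc, n_bp = 1, min_seg = min_seg)
  }
  # a breakpoint within float jitter of a layer boundary belongs to the
  # later layer (half-open convention); snap at 1e-9 before assignment
  psi <- round(fit$psi[1], 9)
  tibble::tibble(
    method = "mathematical", status = "estimated",
    layer_label = layer_of(psi),
    layer_ordinal = as.integer(floor(psi) + 1),
    psi_ell = psi, pattern = cls$pattern,
    fit_method = fit$method, converged = fit$converged, rss = fit$rss,
    reason = NA_character_
  )
}

#' Import visual weaning estimates
#'
#' Validates human visual assignments of the weaning signal and puts them in
#' the same estimates format as [estimate_weaning()], enabling
#' method-agreement analysis. A missing `layer_label` is a `no_signal`
#' record.
#'
#' @param records Tibble with `specimen_id`, `element`, `layer_label`
#'   columns; labels must lie in `L1`-`D5`.
#' @return An estimates tibble with `method = "visual"`.
#' @export
import_visual_estimates <- function(records) {
  needed <- c("specimen_id", "element", "layer_label")
  if (!all(needed %in% names(records))) {
    abort("`records` needs specimen_id, element and layer_label columns.")
  }
  label <- as.character(records$layer_label)
  label[!is.na(label) & label == ""] <- NA_character_
  ordinal <- rep(NA_integer_, length(label))
  present <- !is.na(label)
  if (any(present)) {
    ordinal[present] <- layer_ordinal(label[present])
    bad <- ordinal[present] > 10
    if (any(bad)) {
      abort(sprintf(
        "Visual estimate layer(s) outside L1-D5: %s.",
        paste(unique(label[present][bad]), collapse = ", ")
      ))
    }
  }
  tibble::tibble(
    specimen_id = as.character(records$specimen_id),
    element = as.character(records$element),
    method = "visual",
    status = dplyr::if_else(present, "estimated", "no_signal"),
    layer_label = label,
    layer_ordinal = ordinal,
    psi_ell = NA_real_
  )
}

per_series_apply <- function(data, f) {
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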