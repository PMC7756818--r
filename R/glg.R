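#' Map transect distance onto the continuous growth-layer coordinate
#'
#' Converts each sample's distance along the ablation transect into the
#' continuous layer coordinate `ell` using per-specimen growth-layer
#' annotations. Within a layer the coordinate interpolates linearly
#' (constant growth rate within a layer), so a sample at distance `d` inside
#' layer ordinal `i` spanning `[start, end)` gets
#' `ell = (i - 1) + (d - start) / (end - start)`. Layer intervals are
#' half-open: a sample landing exactly on a boundary belongs to the later
#' layer, since a change detected at a boundary manifests in the newer
#' tissue. Only the first five growth layer groups (`L1`-`D5`, `ell` in
#' `[0, 10)`) are mapped; samples outside the annotated span or beyond `D5`
#' are dropped with a message.
#'
#' @param data Transect tibble with `specimen_id`, `distance_um`, `conc_ppm`
#'   (and usually `element`).
#' @param layers Layer-annotation tibble as returned by
#'   [read_layer_annotations()].
#' @return The tibble with added `ell` and `layer_label` columns, restricted
#'   to mapped samples. Specimens whose series does not overlap their
#'   annotation at all are an error.
#' @examples
#' layers <- tibble::tibble(
#'   specimen_id = "W-001",
#'   layer_label = c("L1", "D1"), start_um = c(0, 200), end_um = c(200, 300),
#'   ordinal = 1:2
#' )
#' x <- tibble::tibble(specimen_id = "W-001",
#'                     distance_um = c(0, 100, 250), conc_ppm = c(400, 380, 300))
#' attach_layer_coordinate(x, layers)
#' @export
attach_layer_coordinate <- function(data, layers) {
  if (!all(c("specimen_id", "distance_um") %in% names(data))) {
    abort("`data` needs `specimen_id` and `distance_um` columns.")
  }
  if (!all(c("specimen_id", "layer_label", "start_um", "end_um") %in% names(layers))) {
    abort("`layers` needs `specimen_id`, `layer_label`, `start_um`, `end_um` columns.")
  }
  if (!"ordinal" %in% names(layers)) layers$ordinal <- layer_ordinal(layers$layer_label)

  ann_by_specimen <- split(
    dplyr::arrange(layers[layers$ordinal <= 10L, ], .data$specimen_id, .data$start_um),
    factor(layers$specimen_id[layers$ordinal <= 10L],
           levels = unique(layers$specimen_id))
  )

  map_one <- function(d) {
    specimen <- d$specimen_id[1]
    ann <- ann_by_specimen[[specimen]]
    if (is.null(ann) || nrow(ann) == 0) {
      abort(sprintf("No layer annotation for specimen %s.", specimen))
    }
    # half-open [start, end): boundary samples go to the later layer
    idx <- findInterval(d$distance_um, ann$start_um)
    inside <- idx >= 1 & d$distance_um < ann$end_um[pmax(idx, 1)]
    if (!any(inside)) {
      abort(sprintf(
        "Series for specimen %s does not overlap its layer annotation.", specimen
      ))
    }
    i <- idx[inside]
    d <- d[inside, , drop = FALSE]
    d$ell <- (ann$ordinal[i] - 1) +
      (d$distance_um - ann$start_um[i]) / (ann$end_um[i] - ann$start_um[i])
    d$layer_label <- ann$layer_label[i]
    d
  }

  parts <- split(data, factor(data$specimen_id, levels = unique(data$specimen_id)))
  out <- dplyr::bind_rows(lapply(parts, map_one))
  dropped <- nrow(data) - nrow(out)
  if (dropped > 0) {
    inform(sprintf(
      "Dropped %d sample(s) outside the annotated first five growth layer groups.",
      dropped
    ))
  }
  tibble::as_tibble(out)
}

#' Restrict registered series to the first five growth layer groups
#'
#' Keeps only samples with `ell < 10` (the first five years of life).
#' [attach_layer_coordinate()] already maps nothing beyond `D5`, so this is
#' idempotent and normally a no-op; it exists as an explicit, checkable
#' restriction and to flag series left too short for smoothing and fitting.
#'
#' @param data Registered tibble with an `ell` column.
#' @param min_points Minimum points per series below which the series is
#'   flagged short; default `window + 2 * min_seg + 1` from `config`.
#' @param config A [weanpoint_config()].
#' @return The truncated tibble; attribute `"short_series"` holds a tibble
#'   of per-series point counts with a logical `short` flag.
#' @export
truncate_to_first_five_glgs <- function(data, min_points = NULL,
                                        config = weanpoint_config()) {
  if (!"ell" %in% names(data)) abort("`data` needs an `ell` column.")
  if (is.null(min_points)) min_points <- config$window + 2 * config$min_seg + 1
  out <- dplyr::filter(data, .data$ell >= 0, .data$ell < 10)
  status <- series_summarise(out, function(d) {
    tibble::tibble(n_points = nrow(d), short = nrow(d) < min_points)
  })
  if (is.data.frame(status) && any(status$short)) {
    inform(sprintf("%d series flagged short (< %d points) after truncation.",
                   sum(status$short), as.integer(min_points)))
  }
  attr(out, "short_series") <- status
  out
}
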