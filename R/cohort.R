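#' Cumulative weaning distribution over years of life
#'
#' A growth layer group spans one year (light + dark layer), so an animal
#' with weaning layer ordinal `<= 2k` weaned by the end of year `k`. This
#' tabulates, per element and method, the percentage of estimable animals
#' weaned by the end of each of the first five years.
#'
#' @param estimates Estimates tibble ([estimate_weaning()] /
#'   [import_visual_estimates()] format). Rows with `no_signal` status are
#'   excluded from the denominator.
#' @return A tibble with columns `year`, `n_weaned_by`, `pct_weaned_by`
#'   (0-100), per (`element`, `method`) group where those columns exist.
#' @examples
#' est <- tibble::tibble(layer_ordinal = c(2L, 4L, 4L, 5L),
#'                       status = "estimated")
#' cumulative_weaning_distribution(est)
#' @export
cumulative_weaning_distribution <- function(estimates) {
  est <- estimated_only(estimates)
  group_apply(est, c("element", "method"), function(d) {
    n <- nrow(d)
    tibble::tibble(
      year = 1:5,
      n_weaned_by = vapply(1:5, function(k) sum(d$layer_ordinal <= 2 * k), integer(1)),
      pct_weaned_by = 100 * vapply(1:5, function(k) mean(d$layer_ordinal <= 2 * k), numeric(1)),
      n_estimated = n
    )
  })
}

#' Median weaning layer
#'
#' The median of the weaning-layer ordinals, with the lower of the two
#' central values for even counts (conservative toward earlier weaning),
#' mapped back to its layer label.
#'
#' @inheritParams cumulative_weaning_distribution
#' @return A tibble with `median_ordinal` and `median_layer`, per
#'   (`element`, `method`) group where present.
#' @examples
#' est <- tibble::tibble(layer_ordinal = c(3L, 4L, 4L, 5L, 9L),
#'                       status = "estimated")
#' median_weaning_layer(est)
#' @export
median_weaning_layer <- function(estimates) {
  est <- estimated_only(estimates)
  group_apply(est, c("element", "method"), function(d) {
    s <- sort(d$layer_ordinal)
    m <- s[ceiling(length(s) / 2)]
    tibble::tibble(median_ordinal = as.integer(m), median_layer = layer_label(m))
  })
}

#' Agreement between two sets of weaning estimates
#'
#' Pairs two estimate sets (visual vs mathematical for one element, or Sr vs
#' Ba for one method) and reports how often they assign the identical growth
#' layer, a layer within one ordinal (about 6 months) and within two
#' ordinals (about a year), plus the maximum ordinal difference. Pairs where
#' either side is `no_signal` are excluded; agreement is defined only over
#' animals both methods could estimate.
#'
#' @param a,b Estimates tibbles.
#' @param by Join keys; defaults to `"specimen_id"` plus `"element"` when
#'   both sides share element values (use `by = "specimen_id"` for
#'   cross-element comparisons).
#' @return One row per group: `n_pairs`, `pct_identical`, `pct_within1`,
#'   `pct_within2`, `max_diff`.
#' @examples
#' a <- tibble::tibble(specimen_id = c("a", "b", "c"),
#'                     layer_ordinal = c(4L, 4L, 2L), status = "estimated")
#' b <- tibble::tibble(specimen_id = c("a", "b", "c"),
#'                     layer_ordinal = c(4L, 5L, 5L), status = "estimated")
#' agreement(a, b)
#' @export
agreement <- function(a, b, by = NULL) {
  if (is.null(by)) {
    shared <- "element" %in% names(a) && "element" %in% names(b) &&
      length(intersect(unique(a$element), unique(b$element))) > 0
    by <- if (shared) c("specimen_id", "element") else "specimen_id"
    by <- intersect(by, intersect(names(a), names(b)))
    if (!length(by)) abort("No shared join keys between `a` and `b`.")
  }
  a2 <- estimated_only(a)[, c(by, "layer_ordinal")]
  b2 <- estimated_only(b)[, c(by, "layer_ordinal")]
  pairs <- dplyr::inner_join(a2, b2, by = by, suffix = c("_a", "_b"),
                             relationship = "one-to-one")
  if (nrow(pairs) == 0) abort("No overlapping estimable pairs between `a` and `b`.")
  d <- abs(pairs$layer_ordinal_a - pairs$layer_ordinal_b)
  tibble::tibble(
    n_pairs = length(d),
    pct_identical = 100 * mean(d == 0),
    pct_within1 = 100 * mean(d <= 1),
    pct_within2 = 100 * mean(d <= 2),
    max_diff = max(d)
  )
}

#' Sex comparison of weaning-layer distributions
#'
#' Pearson chi-squared test (no continuity correction) of the sex-by-
#' weaning-layer contingency table. Only observed layer categories enter the
#' table (empty categories are dropped before computing the degrees of
#' freedom), and sexes with no estimable animals are dropped with a warning.
#' Expected counts below 5 are reported, not blocking.
#'
#' @inheritParams cumulative_weaning_distribution
#' @param meta Specimen metadata tibble ([read_specimen_meta()] format).
#' @return A tibble: `statistic`, `df`, `n`, `p_value`, per (`element`,
#'   `method`) group where present.
#' @export
sex_difference_chisq <- function(estimates, meta) {
  est <- estimated_only(estimates)
  est <- dplyr::inner_join(est, meta[, c("specimen_id", "sex")], by = "specimen_id")
  group_apply(est, c("element", "method"), function(d) {
    tab <- table(d$sex, d$layer_ordinal)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2) abort("Need at least two sexes with estimable animals.")
    if (ncol(tab) < 2) abort("Need at least two observed weaning-layer categories.")
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(res$expected < 5)) {
      inform(sprintf("%d cell(s) with expected count < 5 in the sex table.",
                     sum(res$expected < 5)))
    }
    tibble::tibble(
      statistic = unname(res$statistic),
      df = unname(res$parameter),
      n = sum(tab),
      p_value = unname(res$p.value)
    )
  })
}

#' Weaning estimates by approximate year of birth
#'
#' Descriptive listing of estimates against each animal's approximate birth
#' year (collection year minus rounded age estimate), sorted by birth year.
#' Animals without metadata are retained and flagged, not dropped.
#'
#' @inheritParams sex_difference_chisq
#' @return A tibble: `specimen_id`, `birth_year`, `element`, `method`,
#'   `layer_label`, `layer_ordinal`, `meta_missing`.
#' @export
birth_year_table <- function(estimates, meta) {
  out <- estimates |>
    dplyr::left_join(meta[, c("specimen_id", "birth_year")], by = "specimen_id") |>
    dplyr::mutate(meta_missing = is.na(.data$birth_year)) |>
    dplyr::arrange(.data$birth_year)
  cols <- intersect(
    c("specimen_id", "birth_year", "element", "method",
      "layer_label", "layer_ordinal", "meta_missing"),
    names(out)
  )
  tibble::as_tibble(out[, cols])
}

#' Cohort-level summary of weaning estimates
#'
#' Aggregates per-animal estimates into the cohort outputs: layer counts,
#' cumulative weaning distributions, median layers, visual-vs-mathematical
#' and Sr-vs-Ba agreement, sex chi-squared tests and the birth-year listing.
#'
#' @param estimates Mathematical estimates tibble.
#' @param visual Optional visual estimates tibble.
#' @param meta Optional metadata tibble.
#' @return A list of class `"cohort_summary"` with elements `counts`,
#'   `cumulative`, `median`, `n_by_status`, and (when inputs allow)
#'   `agreement_methods`, `agreement_elements`, `sex_chisq`, `by_birth_year`.
#' @export
summarize_cohort <- function(estimates, visual = NULL, meta = NULL) {
  all_est <- dplyr::bind_rows(estimates[intersect(names(estimates), est_cols())],
                              if (!is.null(visual)) visual[intersect(names(visual), est_cols())])
  est <- estimated_only(all_est)

  counts <- est |>
    dplyr::count(dplyr::pick(dplyr::any_of(c("element", "method", "layer_label"))),
                 name = "n")
  n_by_status <- all_est |>
    dplyr::count(dplyr::pick(dplyr::any_of(c("element", "method", "status"))),
                 name = "n")

  out <- list(
    counts = counts,
    n_by_status = n_by_status,
    cumulative = cumulative_weaning_distribution(all_est),
    median = median_weaning_layer(all_est)
  )

  if (!is.null(visual) && "element" %in% names(estimates)) {
    out$agreement_methods <- dplyr::bind_rows(lapply(
      sort(intersect(unique(estimates$element), unique(visual$element))),
      function(el) {
        dplyr::bind_cols(
          tibble::tibble(element = el),
          agreement(estimates[estimates$element == el, ],
                    visual[visual$element == el, ],
                    by = "specimen_id")
        )
      }
    ))
  }
  if ("element" %in% names(all_est)) {
    els <- sort(unique(all_est$element))
    if (length(els) == 2) {
      out$agreement_elements <- group_apply(
        all_est, "method",
        function(d) {
          a <- d[d$element == els[1], ]
          b <- d[d$element == els[2], ]
          ok <- nrow(estimated_only_safe(a)) > 0 && nrow(estimated_only_safe(b)) > 0
          if (!ok) return(tibble::tibble())
          dplyr::bind_cols(tibble::tibble(elements = paste(els, collapse = " vs ")),
                           agreement(a, b, by = "specimen_id"))
        }
      )
    }
  }
  if (!is.null(meta)) {
    out$sex_chisq <- tryCatch(
      sex_difference_chisq(all_est, meta),
      error = function(e) {
        warn(paste("Sex comparison skipped:", conditionMessage(e)))
        NULL
      }
    )
    out$by_birth_year <- birth_year_table(all_est, meta)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat("Estimates by status:\n")
  print(x$n_by_status, n = 20)
  cat("\nMedian weaning layer:\n")
  print(x$median)
  cat("\nCumulative % weaned by year:\n")
  print(x$cumulative, n = 30)
  if (!is.null(x$agreement_methods)) {
    cat("\nVisual vs mathematical agreement:\n")
    print(x$agreement_methods)
  }
  invisible(x)
}

#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  est <- x$n_by_status
  tibble::tibble(
    n_estimates = sum(est$n),
    n_estimated = sum(est$n[est$status == "estimated"]),
    n_no_signal = sum(est$n[est$status == "no_signal"])
  )
}

est_cols <- function() {
  c("specimen_id", "element", "method", "status",
    "layer_label", "layer_ordinal", "psi_ell")
}

estimated_only <- function(estimates) {
  if (!"layer_ordinal" %in% names(estimates)) {
    abort("Estimates must carry a `layer_ordinal` column.")
  }
  est <- estimates
  if ("status" %in% names(est)) est <- est[est$status == "estimated", ]
  est <- est[!is.na(est$layer_ordinal), ]
  if (nrow(est) == 0) abort("No estimable animals: every estimate is no_signal.")
  est
}

estimated_only_safe <- function(estimates) {
  tryCatch(estimated_only(estimates), error = function(e) estimates[0, ])
}

group_apply <- function(data, keys, f) {
  keys <- intersect(keys, names(data))
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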