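est_tbl <- function(labels) {
  tibble::tibble(
    specimen_id = sprintf("W-%03d", seq_along(labels)),
    status = ifelse(is.na(labels), "no_signal", "estimated"),
    layer_label = labels,
    layer_ordinal = ifelse(is.na(labels), NA_integer_, layer_ordinal(labels))
  )
}

test_that("cumulative weaning distribution counts ordinals by year", {
  cum <- cumulative_weaning_distribution(est_tbl(c("D1", "D2", "D2", "L3")))
  expect_equal(cum$pct_weaned_by, c(25, 75, 100, 100, 100))
  expect_equal(cum$n_weaned_by, c(1L, 3L, 4L, 4L, 4L))

  late <- cumulative_weaning_distribution(est_tbl(rep("D5", 3)))
  expect_equal(late$pct_weaned_by, c(0, 0, 0, 0, 100))

  one <- cumulative_weaning_distribution(est_tbl("L1"))
  expect_equal(one$pct_weaned_by, rep(100, 5))

  expect_error(cumulative_weaning_distribution(est_tbl(NA_character_)),
               "No estimable")
})

test_that("cumulative percentages are nondecreasing and reach 100%", {
  withr::with_seed(61, {
    for (i in 1:5) {
      labels <- layer_label(sample(1:10, 20, replace = TRUE))
      cum <- cumulative_weaning_distribution(est_tbl(labels))
      expect_true(all(diff(cum$pct_weaned_by) >= 0))
      expect_equal(cum$pct_weaned_by[5], 100)
    }
  })
})

test_that("median weaning layer uses the lower middle ordinal", {
  expect_equal(median_weaning_layer(est_tbl(layer_label(c(3, 4, 4, 5, 9))))$median_layer, "D2")
  m <- median_weaning_layer(est_tbl(layer_label(c(3, 4, 5, 6))))
  expect_equal(m$median_ordinal, 4L)  # lower of the two central values
  expect_equal(m$median_layer, "D2")
  expect_equal(median_weaning_layer(est_tbl("L4"))$median_layer, "L4")
})

test_that("agreement on the three-pair worked example", {
  a <- est_tbl(c("D2", "D2", "D1"))
  b <- est_tbl(c("D2", "L3", "L3"))
  ag <- agreement(a, b)
  expect_equal(ag$n_pairs, 3L)
  expect_equal(ag$pct_identical, 100 / 3, tolerance = 1e-10)
  expect_equal(ag$pct_within1, 200 / 3, tolerance = 1e-10)
  expect_equal(ag$pct_within2, 200 / 3, tolerance = 1e-10)
  expect_equal(ag$max_diff, 3L)
})

test_that("agreement of a set with itself is perfect, and no_signal pairs drop", {
  withr::with_seed(71, {
    a <- est_tbl(layer_label(sample(1:10, 15, replace = TRUE)))
    self <- agreement(a, a)
    expect_equal(self$pct_identical, 100)
    expect_equal(self$max_diff, 0L)
  })
  a <- est_tbl(c("D2", NA, "L3"))
  b <- est_tbl(c("D2", "D1", NA))
  ag <- agreement(a, b)
  expect_equal(ag$n_pairs, 1L)
  c1 <- est_tbl(c(NA, NA, NA))
  expect_error(agreement(c1, b), "No (overlapping|estimable)")
})

test_that("sex chi-squared matches the closed form on a 2x2 design", {
  # [[10, 20], [20, 10]]: all expected counts 15, statistic = 4 * 25/15 = 20/3
  est <- est_tbl(c(rep("D1", 30), rep("D2", 30)))
  meta <- tibble::tibble(
    specimen_id = est$specimen_id,
    sex = c(rep("F", 10), rep("M", 20), rep("F", 20), rep("M", 10)),
    birth_year = 2000L
  )
  res <- sex_difference_chisq(est, meta)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$n, 60L)
  expect_equal(res$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE))
})

test_that("identical sex distributions give statistic 0 and p 1", {
  est <- est_tbl(c(rep("D1", 10), rep("D2", 10)))
  meta <- tibble::tibble(specimen_id = est$specimen_id,
                         sex = rep(c("F", "M"), 10))
  res <- suppressMessages(sex_difference_chisq(est, meta))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("degenerate contingency tables error", {
  est <- est_tbl(rep("D1", 10))
  meta <- tibble::tibble(specimen_id = est$specimen_id,
                         sex = rep(c("F", "M"), 5))
  expect_error(sex_difference_chisq(est, meta), "two observed")
  meta2 <- tibble::tibble(specimen_id = est$specimen_id, sex = rep("F", 10))
  est2 <- est_tbl(c(rep("D1", 5), rep("D2", 5)))
  expect_error(sex_difference_chisq(est2, meta2), "two sexes")
})

test_that("the chi-squared statistic ignores row and column order", {
  withr::with_seed(81, {
    labels <- layer_label(sample(2:6, 40, replace = TRUE))
    est <- est_tbl(labels)
    meta <- tibble::tibble(specimen_id = est$specimen_id,
                           sex = sample(c("F", "M"), 40, replace = TRUE))
    r1 <- suppressMessages(sex_difference_chisq(est, meta))
    perm <- sample(nrow(est))
    r2 <- suppressMessages(sex_difference_chisq(est[perm, ], meta))
    expect_equal(r1$statistic, r2$statistic)
    expect_equal(r1$df, r2$df)
  })
})

test_that("the birth-year table derives, orders and flags", {
  est <- est_tbl(c("D2", "D3", "L2"))
  meta <- tibble::tibble(
    specimen_id = c("W-001", "W-002"),
    collection_year = c(2016L, 1990L),
    estimated_age_years = c(10, NA),
    birth_year = c(2006L, NA)
  )
  out <- birth_year_table(est, meta)
  expect_equal(out$birth_year[out$specimen_id == "W-001"], 2006L)
  expect_true(out$meta_missing[out$specimen_id == "W-002"])
  expect_true(out$meta_missing[out$specimen_id == "W-003"])
  expect_equal(nrow(out), 3)  # flagged, not dropped
  # sorted by birth year where known
  two <- birth_year_table(est[1:2, ], tibble::tibble(
    specimen_id = c("W-001", "W-002"), birth_year = c(2006L, 1980L)
  ))
  expect_equal(two$specimen_id, c("W-002", "W-001"))
})

test_that("summarize_cohort assembles counts that conserve animals", {
  est <- dplyr::bind_cols(est_tbl(c("D2", "D2", "L3", NA)),
                          tibble::tibble(element = "Sr88", method = "mathematical"))
  vis <- dplyr::bind_cols(est_tbl(c("D2", "L3", "L3", "D1")),
                          tibble::tibble(element = "Sr88", method = "visual"))
  s <- summarize_cohort(est, visual = vis)
  g <- glance(s)
  expect_equal(g$n_estimates, 8L)
  expect_equal(g$n_estimated + g$n_no_signal, 8L)
  expect_equal(sum(s$counts$n), g$n_estimated)
  expect_equal(s$agreement_methods$n_pairs, 3L)
})
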