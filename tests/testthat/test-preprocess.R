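test_that("half-LOD substitution replaces strictly-below-LOD values only", {
  x <- tibble::tibble(conc_ppm = c(0.10, 0.50, 0.20))
  out <- substitute_below_lod(x, lod = 0.34)
  expect_equal(out$conc_ppm, c(0.17, 0.50, 0.17))
  expect_equal(cleaning_report(out)$n_below_lod, 2)
  expect_equal(cleaning_report(out)$lod_used, 0.34)

  # all at or above the limit: unchanged, including the boundary value
  y <- tibble::tibble(conc_ppm = c(0.34, 0.50, 1.0))
  out2 <- substitute_below_lod(y, lod = 0.34)
  expect_equal(out2$conc_ppm, y$conc_ppm)
  expect_equal(cleaning_report(out2)$n_below_lod, 0)

  expect_error(substitute_below_lod(x, lod = 0), "positive")
  expect_error(substitute_below_lod(x, lod = -1), "positive")
})

test_that("half-LOD substitution is idempotent", {
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- tibble::tibble(conc_ppm = abs(rnorm(50, 0.4, 0.3)))
      lod <- runif(1, 0.05, 0.6)
      once <- substitute_below_lod(x, lod)
      twice <- substitute_below_lod(once, lod)
      expect_equal(twice$conc_ppm, once$conc_ppm)
    }
  })
})

test_that("per-row lod_ppm column is used when no scalar limit is given", {
  x <- tibble::tibble(conc_ppm = c(0.1, 0.1), lod_ppm = c(0.34, 0.05))
  out <- substitute_below_lod(x)
  expect_equal(out$conc_ppm, c(0.17, 0.1))
})

test_that("the 4-SD rule removes a spike whose z-score exceeds 4", {
  vals <- c(rep(10, 100), 20)
  # brute-force oracle: z-score from the plain mean/SD of the vector
  z <- abs(vals - mean(vals)) / sd(vals)
  expect_gt(z[101], 4)
  out <- remove_outliers(tibble::tibble(conc_ppm = vals), k = 4)
  expect_equal(nrow(out), 100)
  expect_equal(cleaning_report(out)$n_outliers_removed, 1)
  expect_equal(cleaning_report(out)$outlier_indices[[1]], 101L)
})

test_that("outlier removal is a single pass over the full series", {
  # after removing the extreme spike a second pass would flag more points;
  # a single-pass rule must not
  vals <- c(rep(10, 50), 11.5, rep(10, 49), 50)
  out <- remove_outliers(tibble::tibble(conc_ppm = vals), k = 4)
  removed <- setdiff(seq_along(vals), which(vals %in% out$conc_ppm))
  expect_equal(cleaning_report(out)$n_outliers_removed, 1)
  expect_true(11.5 %in% out$conc_ppm)
})

test_that("outlier removal handles degenerate series", {
  const <- tibble::tibble(conc_ppm = rep(5, 10))
  out <- remove_outliers(const)
  expect_equal(nrow(out), 10)
  expect_equal(cleaning_report(out)$n_outliers_removed, 0)
  expect_error(remove_outliers(tibble::tibble(conc_ppm = c(1, 2))), "at least 3")
  expect_error(remove_outliers(tibble::tibble(conc_ppm = 1:5), k = 0), "positive")
})

test_that("a sample equal to the series mean is never removed", {
  withr::with_seed(31, {
    for (i in 1:10) {
      v <- rnorm(30, 100, 20)
      v[15] <- sum(v[-15]) / 29  # v[15] == mean(v) by construction
      out <- remove_outliers(tibble::tibble(conc_ppm = v), k = 0.5)
      expect_true(v[15] %in% out$conc_ppm)
    }
  })
})

test_that("Savitzky-Golay reproduces a cubic exactly at interior points", {
  x <- seq(0, 3, length.out = 31)
  d <- tibble::tibble(conc_ppm = x^3)
  sm <- savgol_smooth(d, window = 15, polyorder = 3)
  expect_equal(nrow(sm), 31 - 14)
  expect_lt(max(abs(sm$conc_ppm - x[8:24]^3)), 1e-9)
})

test_that("smoothing a constant changes nothing but trims the edges", {
  d <- tibble::tibble(conc_ppm = rep(7, 40))
  sm <- savgol_smooth(d)
  expect_equal(nrow(sm), 40 - 14)
  expect_equal(sm$conc_ppm, rep(7, 26))
})

test_that("short series cannot be smoothed", {
  d <- tibble::tibble(conc_ppm = rnorm(10))
  expect_error(savgol_smooth(d, window = 15), "short series")
})

test_that("the smoother is linear: commutes with shifts and scales", {
  withr::with_seed(41, {
    y <- rnorm(60)
    base <- savgol_smooth(tibble::tibble(conc_ppm = y))$conc_ppm
    shifted <- savgol_smooth(tibble::tibble(conc_ppm = y + 11))$conc_ppm
    scaled <- savgol_smooth(tibble::tibble(conc_ppm = 3 * y))$conc_ppm
    expect_equal(shifted, base + 11)
    expect_equal(scaled, 3 * base)
  })
})

test_that("cleaning operates per series on a multi-series table", {
  d <- tibble::tibble(
    specimen_id = rep(c("A", "B"), each = 50),
    element = "Sr88",
    conc_ppm = c(rep(10, 49), 30, rep(20, 50))
  )
  out <- remove_outliers(d, k = 4)
  rep <- cleaning_report(out)
  expect_equal(rep$n_outliers_removed[rep$specimen_id == "A"], 1)
  expect_equal(rep$n_outliers_removed[rep$specimen_id == "B"], 0)
  expect_equal(nrow(out), 99)
})
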