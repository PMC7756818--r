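test_that("fit_line recovers exact lines and degenerates sensibly", {
  x <- seq(0, 4, by = 0.5)
  f <- fit_line(x, 1 + 2 * x)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$slopes, 2, tolerance = 1e-10)
  expect_lt(f$rss, 1e-20)
  expect_equal(fit_line(x, rep(3, length(x)))$slopes, 0)
  expect_lt(fit_line(c(0, 1), c(5, 9))$rss, 1e-20)
  expect_error(fit_line(rep(1, 5), 1:5), "distinct")
})

test_that("both fitters recover an exact two-segment profile", {
  x <- seq(0, 4, by = 0.25)
  y <- ifelse(x <= 2, 8 - 3 * x, 2)
  for (f in list(fit_segmented_grid(x, y, 1), fit_segmented_iterative(x, y, 1))) {
    expect_equal(f$psi, 2, tolerance = 1e-6)
    expect_equal(f$slopes, c(-3, 0), tolerance = 1e-6)
    expect_lt(f$rss, 1e-12 * var(y))
  }
})

test_that("a pure line is flagged non-identifiable and selection prefers no breakpoint", {
  x <- seq(0, 4, by = 0.25)
  y <- 1 + 2 * x
  it <- fit_segmented_iterative(x, y, 1)
  expect_false(it$converged)
  expect_match(it$diagnostic, "slope")
  best <- select_breakpoint_model(x, y)
  expect_equal(best$n_breakpoints, 0L)
})

test_that("the 2-breakpoint grid recovers an exact three-segment profile", {
  x <- seq(0, 8, by = 0.1)
  y <- ifelse(x <= 2, 10 - 3 * x, ifelse(x <= 5, 4 - 0.5 * (x - 2), 2.5))
  f <- fit_segmented_grid(x, y, 2, grid_size = Inf)
  expect_equal(f$psi, c(2, 5), tolerance = 1e-9)
  expect_equal(f$slopes, c(-3, -0.5, 0), tolerance = 1e-8)
  expect_lt(f$rss, 1e-12 * var(y))
})

test_that("grid rss is monotone in model complexity and ties resolve early", {
  s <- make_noisy_series("P2", 0.05, seed = 77)
  f0 <- fit_line(s$x, s$y)
  f1 <- fit_segmented_grid(s$x, s$y, 1)
  f2 <- fit_segmented_grid(s$x, s$y, 2)
  expect_lte(f1$rss, f0$rss)
  expect_lte(f2$rss, f1$rss * (1 + 1e-10))
  # constant response: every candidate fits exactly; earliest wins
  x <- seq(0, 10, length.out = 50)
  tie <- fit_segmented_grid(x, rep(2, 50), 1, min_seg = 5)
  expect_equal(tie$psi, x[5])
})

test_that("iterative matches the grid oracle or flags itself on noisy data", {
  ok <- vapply(1:40, function(i) {
    pat <- c("P1", "P2", "P3", "P4")[(i - 1) %% 4 + 1]
    s <- make_noisy_series(pat, if (i %% 2) 0 else 0.05, seed = 500 + i)
    it <- fit_segmented_iterative(s$x, s$y, 1)
    gr <- fit_segmented_grid(s$x, s$y, 1)
    it$rss <= gr$rss * (1 + 1e-6) || !it$converged
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("fitted models are continuous at their breakpoints", {
  s <- make_noisy_series("P2", 0.05, seed = 3)
  f <- fit_segmented_iterative(s$x, s$y, 1)
  eps <- 1e-9
  left <- predict(f, f$psi - eps)
  right <- predict(f, f$psi + eps)
  expect_lt(abs(left - right), 1e-6)
  f2 <- fit_segmented_grid(s$x, s$y, 2)
  expect_lt(max(abs(predict(f2, f2$psi - eps) - predict(f2, f2$psi + eps))), 1e-6)
})

test_that("input order does not change the fit", {
  s <- make_noisy_series("P2", 0.05, seed = 9)
  perm <- sample(seq_along(s$x))
  f1 <- fit_segmented_grid(s$x, s$y, 1)
  f2 <- fit_segmented_grid(s$x[perm], s$y[perm], 1)
  expect_equal(f1$psi, f2$psi)
  expect_equal(f1$rss, f2$rss)
  i1 <- fit_segmented_iterative(s$x, s$y, 1)
  i2 <- fit_segmented_iterative(s$x[perm], s$y[perm], 1)
  expect_equal(i1$psi, i2$psi)
})

test_that("breakpoint error shrinks as noise vanishes", {
  x <- seq(0, 4, by = 0.02)
  trend <- ifelse(x <= 2, 8 - 3 * x, 2)
  med_err <- vapply(c(0.1, 0.01, 0.001), function(frac) {
    sigma <- frac * diff(range(trend))
    errs <- vapply(1:20, function(i) {
      set.seed(6000 + round(1e4 * frac) + i)
      f <- fit_segmented_iterative(x, trend + rnorm(length(x), 0, sigma), 1)
      abs(f$psi - 2)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
  expect_lt(med_err[3], 0.02)
})

test_that("BIC selection identifies the true breakpoint count in simulation", {
  x <- seq(0, 10, length.out = 300)
  trend1 <- ifelse(x <= 4, 400 - 50 * x, 200)
  picks1 <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    y <- trend1 * exp(rnorm(300, 0, 0.05))
    select_breakpoint_model(x, y)$n_breakpoints
  }, integer(1))
  expect_gte(mean(picks1 == 1L), 0.9)

  picks0 <- vapply(1:200, function(i) {
    set.seed(8000 + i)
    y <- (300 - 5 * x) * exp(rnorm(300, 0, 0.05))
    select_breakpoint_model(x, y)$n_breakpoints
  }, integer(1))
  expect_gt(mean(picks0 == 0L), 0.5)

  # exact two-segment data (break on the grid): 1 breakpoint wins over 2
  xg <- (0:299) / 30
  yg <- ifelse(xg <= 4, 400 - 50 * xg, 200)
  expect_equal(select_breakpoint_model(xg, yg)$n_breakpoints, 1L)
})

test_that("select_model validates its inputs", {
  x <- seq(0, 10, length.out = 50)
  f1 <- fit_line(x, 2 * x)
  f2 <- fit_line(x[-1], 2 * x[-1])
  expect_error(select_model(list()), "non-empty")
  expect_error(select_model(list(f1, f2)), "identical data")
  expect_error(select_model(list(f1, "no")), "breakpoint_fit")
})

test_that("tidy, glance and predict expose the fit", {
  x <- seq(0, 4, by = 0.25)
  y <- ifelse(x <= 2, 8 - 3 * x, 2)
  f <- fit_segmented_grid(x, y, 1)
  td <- tidy(f)
  expect_setequal(td$term, c("intercept", "slope1", "slope2", "psi1"))
  expect_equal(td$estimate[td$term == "psi1"], 2)
  gl <- glance(f)
  expect_equal(gl$n_breakpoints, 1L)
  expect_equal(gl$n_points, length(x))
  expect_equal(predict(f, c(0, 2, 4)), c(8, 2, 2), tolerance = 1e-8)
})
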