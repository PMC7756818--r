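test_that("identical parameters and seed give bit-identical animals", {
  a <- simulate_animal(pattern = "P2", seed = 42)
  b <- simulate_animal(pattern = "P2", seed = 42)
  expect_identical(a, b)
  c <- simulate_animal(pattern = "P2", seed = 43)
  expect_false(identical(a$transects$conc_ppm, c$transects$conc_ppm))
})

test_that("a noiseless P2 animal is exactly piecewise linear with the stated break", {
  params <- generator_params(noise_sigma = 0, spike_rate = 0)
  a <- simulate_animal(params, pattern = "P2", seed = 7)
  tr <- a$transects[a$transects$element == "Sr88", ]
  reg <- suppressMessages(attach_layer_coordinate(tr, a$layers))
  f <- fit_segmented_grid(reg$ell, reg$conc_ppm, 1)
  spacing <- max(diff(sort(reg$ell)))
  expect_lt(abs(f$psi - a$truth$psi_weaning[1]), spacing + 1e-12)
  # the true break lies between samples, so the fit pins it to the nearest
  # grid point; the leftover rss is bounded by the one-sample corner error
  expect_lt(f$rss, 1e-6 * sum((reg$conc_ppm - mean(reg$conc_ppm))^2))
  expect_equal(f$coefficients[["(Intercept)"]], 400, tolerance = 1e-3)
})

test_that("a noiseless P1 animal carries both of its recorded breaks", {
  params <- generator_params(noise_sigma = 0, spike_rate = 0)
  a <- simulate_animal(params, pattern = "P1", seed = 19)
  tr <- a$transects[a$transects$element == "Ba137", ]
  reg <- suppressMessages(attach_layer_coordinate(tr, a$layers))
  sub <- reg[seq(1, nrow(reg), by = 8), ]
  f <- fit_segmented_grid(sub$ell, sub$conc_ppm, 2, grid_size = 250)
  spacing <- max(diff(sub$ell))
  expect_lt(abs(f$psi[1] - a$truth$psi_weaning[1]), spacing + 1e-12)
  expect_lt(abs(f$psi[2] - a$truth$psi_second[1]), spacing + 1e-12)
})

test_that("P4 animals fall below the decline threshold by construction", {
  cfg <- weanpoint_config()
  for (seed in 1:5) {
    a <- simulate_animal(pattern = "P4", seed = seed)
    tr <- a$transects[a$transects$element == "Sr88", ]
    n <- nrow(tr)
    dec_n <- max(1, floor(cfg$decile * n))
    d <- mean(tr$conc_ppm[1:dec_n]) - mean(tr$conc_ppm[(n - dec_n + 1):n])
    expect_lt(d, cfg$decline_frac * stats::IQR(tr$conc_ppm))
  }
})

test_that("cohorts have complete truth tables and multinomial pattern draws", {
  co <- cached_cohort(100, seed = 11)
  expect_equal(sum(co$truth$element == "Sr88"), 100)
  expect_equal(sum(co$truth$element == "Ba137"), 100)
  expect_equal(nrow(co$meta), 100)
  expect_true(all(table(co$truth$pattern) > 0))
  expect_error(simulate_cohort(0), ">= 1")
})

test_that("empirical pattern frequencies approach their probabilities", {
  co <- cached_cohort(1000, seed = 3)
  freq <- table(factor(co$truth$pattern[co$truth$element == "Sr88"],
                       levels = c("P1", "P2", "P3", "P4"))) / 1000
  probs <- c(0.41, 0.43, 0.10, 0.06)
  expect_true(all(abs(as.numeric(freq) - probs) < 0.04))
})

test_that("a 200-animal cohort covers all patterns and weaning layers 2-8", {
  co <- cached_cohort(200, seed = 1)
  expect_setequal(unique(co$truth$pattern), c("P1", "P2", "P3", "P4"))
  weaned <- unique(co$truth$weaning_ordinal[!is.na(co$truth$weaning_ordinal)])
  expect_true(all(2:8 %in% weaned))
})

test_that("truth records reconstruct from generated files alone", {
  # censoring: raise the Ba detection limit so some plateau values censor
  params <- generator_params(
    elements = list(Sr88 = list(start_ppm = 400, end_ppm = 200, lod_ppm = 0.18),
                    Ba137 = list(start_ppm = 10, end_ppm = 5, lod_ppm = 6))
  )
  a <- simulate_animal(params, pattern = "P2", seed = 23)
  ba <- a$transects[a$transects$element == "Ba137", ]
  expect_equal(a$truth$n_censored[a$truth$element == "Ba137"],
               sum(ba$conc_ppm < 6))
  expect_gt(a$truth$n_censored[a$truth$element == "Ba137"], 0)
  # spikes: recorded indices point at the inflated samples
  tr <- a$transects[a$transects$element == "Sr88", ]
  idx <- as.integer(strsplit(a$truth$spike_indices[a$truth$element == "Sr88"],
                             ";")[[1]])
  truth_sr <- a$truth[a$truth$element == "Sr88", ]
  expect_equal(length(idx), truth_sr$n_spikes)
  if (length(idx)) expect_true(all(tr$conc_ppm[idx] >
                                     3 * stats::median(tr$conc_ppm)))
})

test_that("pseudo-visual estimates follow their error model", {
  truth <- tibble::tibble(
    specimen_id = sprintf("S%03d", 1:500),
    element = "Sr88",
    weaning_ordinal = sample(2:8, 500, replace = TRUE)
  )
  exact <- pseudo_visual(truth, p_error = 0, seed = 1)
  expect_equal(layer_ordinal(exact$layer_label), truth$weaning_ordinal)

  always <- pseudo_visual(truth, p_error = 1, seed = 2)
  diff1 <- abs(layer_ordinal(always$layer_label) - truth$weaning_ordinal)
  expect_true(all(diff1 == 1))

  default <- pseudo_visual(truth, p_error = 0.2, seed = 3)
  identical_frac <- mean(layer_ordinal(default$layer_label) == truth$weaning_ordinal)
  expect_lt(abs(identical_frac - 0.8), 0.05)

  no_layer <- pseudo_visual(tibble::tibble(specimen_id = "a", element = "Sr88",
                                           weaning_ordinal = NA_integer_),
                            seed = 4)
  expect_true(is.na(no_layer$layer_label))
})

test_that("generator parameters validate", {
  expect_error(generator_params(nope = 1), "Unknown generator parameter")
  expect_error(generator_params(pattern_probs = c(P1 = 0.5, P2 = 0.6, P3 = 0, P4 = 0)),
               "sum to 1")
  expect_error(generator_params(noise_sigma = -1), ">= 0")
  expect_error(simulate_animal(pattern = "P9"), "P1, P2, P3, P4")
})
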