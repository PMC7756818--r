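# Shared fixtures, built in code.

# Noiseless exemplar profiles of the four accumulation patterns on a regular
# layer-coordinate grid. Breakpoints sit exactly on grid points so exact
# fits (rss ~ 0) are attainable.
make_exemplar <- function(pattern, n = 401) {
  ell <- seq(0, 10, length.out = n)
  conc <- switch(pattern,
    # steep decline to ell 2, shallow decline to ell 6, then stable
    P1 = ifelse(ell <= 2, 400 - 90 * ell,
         ifelse(ell <= 6, 220 - 10 * (ell - 2), 180)),
    # steep decline to ell 3, then stable
    P2 = ifelse(ell <= 3, 400 - 100 * ell, 100),
    # smooth curvilinear decline, no change point
    P3 = 200 + 200 * exp(-ell / 3),
    # no decline
    P4 = rep(300, n),
    stop("unknown pattern")
  )
  tibble::tibble(ell = ell, conc_ppm = conc)
}

# Synthetic series for fitter checks: piecewise-linear + multiplicative
# log-normal noise, random breakpoint(s).
make_noisy_series <- function(pattern, sigma, seed, n = 400) {
  set.seed(seed)
  x <- seq(0, 10, length.out = n)
  psi1 <- runif(1, 1.5, 6)
  psi2 <- psi1 + runif(1, 1.5, 3)
  y <- switch(pattern,
    P1 = ifelse(x <= psi1, 400 - 170 / psi1 * x,
         ifelse(x <= psi2, 230 - 30 * (x - psi1) / (psi2 - psi1), 200)),
    P2 = ifelse(x <= psi1, 400 - 200 / psi1 * x, 200),
    P3 = 200 + 200 * exp(-x / 3),
    P4 = rep(300, n)
  )
  list(x = x, y = y * exp(rnorm(n, 0, sigma)), psi1 = psi1, psi2 = psi2)
}

# One cohort per (n, seed), cached for the test session.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(n, seed = seed)
  }
  .cohort_cache[[key]]
}

.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(n, seed) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.pipeline_cache[[key]])) {
    co <- cached_cohort(n, seed)
    .pipeline_cache[[key]] <-
      suppressMessages(run_weaning_pipeline(co$transects, co$layers))
  }
  .pipeline_cache[[key]]
}

# Minimal valid input files for reader tests.
write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
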