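#' Continuous piecewise-linear (segmented) regression
#'
#' The weaning signal is the change point at which a declining element
#' concentration transitions to stable adult values. These fitters estimate
#' continuous piecewise-linear models with 0, 1 or 2 breakpoints:
#'
#' * [fit_line()] — ordinary least squares, the 0-breakpoint null model;
#' * [fit_segmented_iterative()] — the iterative breakpoint-update
#'   algorithm: at each step the model is linearized around the current
#'   breakpoint by regressing on the hinge term `(x - psi)+` plus a gap
#'   indicator, and the breakpoint moves by the ratio of the gap coefficient
#'   to the slope-change coefficient, with step-halving whenever the update
#'   would increase the residual sum of squares;
#' * [fit_segmented_grid()] — an exhaustive grid search over observed
#'   interior abscissa values, the deterministic oracle against which the
#'   iterative fitter is validated;
#' * [select_model()] / [select_breakpoint_model()] — BIC selection among
#'   the 0/1/2-breakpoint candidates.
#'
#' All fitters return a `breakpoint_fit` object with [tidy()], [glance()],
#' [predict()] and [autoplot()] methods.
#'
#' @name segmented-regression
NULL

new_breakpoint_fit <- function(n_breakpoints, psi, coefficients, rss, n_points,
                               converged, n_iter, method, x_range,
                               diagnostic = NA_character_) {
  slopes <- cumsum(coefficients[-1])
  structure(
    list(
      n_breakpoints = as.integer(n_breakpoints),
      psi = as.numeric(psi),
      intercept = unname(coefficients[1]),
      slopes = unname(slopes),
      coefficients = coefficients,
      rss = rss,
      n_points = as.integer(n_points),
      converged = converged,
      n_iter = n_iter,
      method = method,
      x_range = x_range,
      bic = breakpoint_bic(rss, n_points, n_breakpoints),
      diagnostic = diagnostic
    ),
    class = "breakpoint_fit"
  )
}

breakpoint_bic <- function(rss, n, n_bp) {
  p <- 2 + 2 * n_bp
  # rss of 0 (exact fit) maps to -Inf, which correctly dominates selection
  n * log(rss / n) + p * log(n)
}

segmented_design <- function(x, psi) {
  X <- cbind(1, x)
  for (p in psi) X <- cbind(X, pmax(x - p, 0))
  X
}

#' Fitted values from a breakpoint fit
#'
#' @param object A `breakpoint_fit`.
#' @param newdata Optional numeric vector of abscissa values; defaults to
#'   nothing (an error), since the fit does not retain its data.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.breakpoint_fit <- function(object, newdata, ...) {
  if (missing(newdata)) abort("Supply `newdata` (abscissa values) to predict.")
  drop(segmented_design(as.numeric(newdata), object$psi) %*% object$coefficients)
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("<breakpoint_fit: %d breakpoint(s), %s>\n",
              x$n_breakpoints, x$method))
  if (x$n_breakpoints > 0) {
    cat("  psi:    ", paste(format(x$psi, digits = 6), collapse = ", "), "\n")
  }
  cat("  slopes: ", paste(format(x$slopes, digits = 6), collapse = ", "), "\n")
  cat(sprintf("  rss %.6g on %d points; BIC %.2f; converged: %s\n",
              x$rss, x$n_points, x$bic, x$converged))
  invisible(x)
}

#' @rdname segmented-regression
#' @param x,y Numeric vectors of equal length; `x` is sorted internally.
#' @export
fit_line <- function(x, y) {
  xy <- check_xy(x, y, min_n = 2)
  if (length(unique(xy$x)) < 2) abort("Need at least 2 distinct x values.")
  fit <- lm.fit(cbind(1, xy$x), xy$y)
  new_breakpoint_fit(
    n_breakpoints = 0L, psi = numeric(0),
    coefficients = setNames(coef(fit), c("(Intercept)", "x")),
    rss = sum(fit$residuals^2), n_points = length(xy$x),
    converged = TRUE, n_iter = 0L, method = "ols",
    x_range = range(xy$x)
  )
}

#' @rdname segmented-regression
#' @param n_bp Number of breakpoints (1 or 2; [fit_line()] covers 0).
#' @param psi0 Starting breakpoint(s). The default tries several interior
#'   quantiles of `x` as starts and keeps the best converged fit: the rss
#'   profile over the breakpoint can have several local minima (for example
#'   when the underlying profile has two slope changes), and a single
#'   midrange start can settle in the wrong one.
#' @param tol Convergence tolerance on the breakpoint move, relative to
#'   `diff(range(x))`.
#' @param max_iter Iteration cap.
#' @param min_seg Minimum data points required on each side of (and between)
#'   breakpoints; prevents boundary-hugging solutions.
#' @export
fit_segmented_iterative <- function(x, y, n_bp = 1, psi0 = NULL, tol = 1e-8,
                                    max_iter = 50, min_seg = 5) {
  if (is.null(psi0)) {
    starts <- if (as.integer(n_bp) == 1) {
      as.list(quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
    } else {
      qs <- quantile(x, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
      list(qs[c(1, 3)], qs[c(2, 4)], qs[c(1, 4)])
    }
    fits <- lapply(starts, function(p0) {
      fit_segmented_iterative(x, y, n_bp = n_bp, psi0 = p0, tol = tol,
                              max_iter = max_iter, min_seg = min_seg)
    })
    conv <- vapply(fits, `[[`, logical(1), "converged")
    rss <- vapply(fits, `[[`, numeric(1), "rss")
    pick <- if (any(conv)) which(conv)[which.min(rss[conv])] else which.min(rss)
    return(fits[[pick]])
  }
  n_bp <- as.integer(n_bp)
  if (!n_bp %in% 1:2) abort("`n_bp` must be 1 or 2.")
  xy <- check_xy(x, y, min_n = (n_bp + 1) * min_seg + 1)
  x <- xy$x; y <- xy$y
  n <- length(x)
  lo <- x[min_seg]
  hi <- x[n - min_seg + 1]
  if (lo >= hi) abort("Too few distinct x values for the requested min_seg.")

  psi <- pmin(pmax(sort(as.numeric(psi0)), lo), hi)
  if (length(psi) != n_bp) abort("`psi0` must supply one value per breakpoint.")

  cont_rss <- function(psi) {
    fit <- lm.fit(segmented_design(x, psi), y)
    sum(fit$residuals^2)
  }

  rss_old <- cont_rss(psi)
  converged <- FALSE
  diagnostic <- NA_character_
  iter <- 0L
  x_span <- diff(range(x))
  y_scale <- sd(y)
  if (y_scale == 0) y_scale <- 1

  while (iter < max_iter) {
    iter <- iter + 1L
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
    V <- vapply(psi, function(p) -as.numeric(x > p), numeric(n))
    work <- lm.fit(cbind(1, x, U, V), y)
    cf <- coef(work)
    beta <- cf[2 + seq_len(n_bp)]
    gamma <- cf[2 + n_bp + seq_len(n_bp)]
    beta[is.na(beta)] <- 0
    gamma[is.na(gamma)] <- 0
    if (any(abs(beta) < 1e-10 * y_scale / x_span)) {
      diagnostic <- "slope-change coefficient ~ 0: breakpoint not identifiable"
      break
    }
    step <- gamma / beta
    # step-halving: accept the first step (possibly halved) that does not
    # increase the continuous-model rss
    accepted <- FALSE
    for (h in 0:12) {
      psi_new <- sort(pmin(pmax(psi + step / 2^h, lo), hi))
      rss_new <- cont_rss(psi_new)
      if (rss_new <= rss_old * (1 + 1e-12) || h == 12) {
        accepted <- TRUE
        break
      }
    }
    moved <- max(abs(psi_new - psi))
    psi <- psi_new
    rss_old <- min(rss_old, rss_new)
    if (moved < tol * x_span) {
      converged <- TRUE
      break
    }
  }
  if (!converged && is.na(diagnostic)) {
    diagnostic <- sprintf("no convergence in %d iterations", max_iter)
  }

  # a breakpoint is only identified if its slope change is distinguishable
  # from zero; on no-signal (flat-noise) data the update settles in an
  # arbitrary local minimum and must be flagged rather than trusted
  if (converged) {
    Xw <- segmented_design(x, psi)
    fitw <- lm.fit(Xw, y)
    dfres <- n - ncol(Xw)
    if (dfres > 0) {
      sigma2 <- sum(fitw$residuals^2) / dfres
      XtX_inv <- tryCatch(chol2inv(chol(crossprod(Xw))), error = function(e) NULL)
      if (!is.null(XtX_inv)) {
        hinge_idx <- 2 + seq_len(n_bp)
        se <- sqrt(sigma2 * diag(XtX_inv)[hinge_idx])
        bhat <- coef(fitw)[hinge_idx]
        bhat[is.na(bhat)] <- 0
        weak <- se > 0 & abs(bhat) < 2 * se
        if (any(weak)) {
          converged <- FALSE
          diagnostic <- "slope change not distinguishable from zero at the fitted breakpoint"
        }
      }
    }
  }

  # final continuous refit (no gap term) at the converged breakpoint(s)
  final <- lm.fit(segmented_design(x, psi), y)
  cf <- coef(final)
  cf[is.na(cf)] <- 0
  new_breakpoint_fit(
    n_breakpoints = n_bp, psi = psi,
    coefficients = setNames(cf, c("(Intercept)", "x", paste0("hinge", seq_len(n_bp)))),
    rss = sum(final$residuals^2), n_points = n,
    converged = converged, n_iter = iter, method = "iterative",
    x_range = range(x), diagnostic = diagnostic
  )
}

#' @rdname segmented-regression
#' @param grid_size Maximum number of candidate breakpoint locations per
#'   axis. The candidate set is the observed interior `x` values honouring
#'   `min_seg`; when it exceeds `grid_size` it is thinned to an evenly
#'   spaced subset (by default only for the 2-breakpoint search, whose grid
#'   is all ordered candidate pairs).
#' @export
fit_segmented_grid <- function(x, y, n_bp = 1, min_seg = 5,
                               grid_size = if (n_bp == 1) Inf else 80) {
  n_bp <- as.integer(n_bp)
  if (!n_bp %in% 1:2) abort("`n_bp` must be 1 or 2.")
  xy <- check_xy(x, y, min_n = (n_bp + 1) * min_seg + 1)
  x <- xy$x; y <- xy$y
  n <- length(x)

  # suffix sums: T*(k) = sum over samples strictly after position k
  sfx <- function(v) c(rev(cumsum(rev(v)))[-1], 0)
  T0 <- sfx(rep(1, n)); T1 <- sfx(x); T2 <- sfx(x * x)
  Ty <- sfx(y); Txy <- sfx(x * y)
  Sx <- sum(x); Sxx <- sum(x * x); Sy <- sum(y); Sxy <- sum(x * y)

  cand <- seq(min_seg, n - min_seg)
  if (n_bp == 1) {
    ks <- thin_indices(cand, grid_size)
    psi <- x[ks]
    Su <- T1[ks] - psi * T0[ks]
    Suu <- T2[ks] - 2 * psi * T1[ks] + psi^2 * T0[ks]
    Sxu <- T2[ks] - psi * T1[ks]
    Syu <- Txy[ks] - psi * Ty[ks]
    # Cramer's rule on the symmetric 3x3 normal equations, vectorized over
    # candidates; rss differences only rank candidates (the winner is refit
    # exactly below)
    a11 <- n; a12 <- Sx; a13 <- Su
    a22 <- Sxx; a23 <- Sxu; a33 <- Suu
    det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    r1 <- Sy; r2 <- Sxy; r3 <- Syu
    b1 <- (r1 * (a22 * a33 - a23^2) - a12 * (r2 * a33 - a23 * r3) +
             a13 * (r2 * a23 - a22 * r3)) / det
    b2 <- (a11 * (r2 * a33 - r3 * a23) - r1 * (a12 * a33 - a23 * a13) +
             a13 * (a12 * r3 - r2 * a13)) / det
    b3 <- (a11 * (a22 * r3 - a23 * r2) - a12 * (a12 * r3 - r2 * a13) +
             r1 * (a12 * a23 - a22 * a13)) / det
    rss <- sum(y * y) - (b1 * r1 + b2 * r2 + b3 * r3)
    rss[!is.finite(rss) | abs(det) < .Machine$double.eps * n * Sxx] <- Inf
    best <- which.min(rss)  # first minimum = earliest breakpoint on ties
    psi_best <- psi[best]
  } else {
    ks <- thin_indices(cand, grid_size)
    best_pair <- NULL
    best_rss <- Inf
    yy <- sum(y * y)
    for (i in seq_along(ks)) {
      k1 <- ks[i]
      k2s <- ks[ks >= k1 + min_seg & ks <= n - min_seg]
      if (!length(k2s)) next
      p1 <- x[k1]
      Su1 <- T1[k1] - p1 * T0[k1]
      Su1u1 <- T2[k1] - 2 * p1 * T1[k1] + p1^2 * T0[k1]
      Sxu1 <- T2[k1] - p1 * T1[k1]
      Syu1 <- Txy[k1] - p1 * Ty[k1]
      for (k2 in k2s) {
        p2 <- x[k2]
        Su2 <- T1[k2] - p2 * T0[k2]
        Su2u2 <- T2[k2] - 2 * p2 * T1[k2] + p2^2 * T0[k2]
        Sxu2 <- T2[k2] - p2 * T1[k2]
        Syu2 <- Txy[k2] - p2 * Ty[k2]
        Su1u2 <- T2[k2] - (p1 + p2) * T1[k2] + p1 * p2 * T0[k2]
        M <- matrix(c(
          n,   Sx,   Su1,   Su2,
          Sx,  Sxx,  Sxu1,  Sxu2,
          Su1, Sxu1, Su1u1, Su1u2,
          Su2, Sxu2, Su1u2, Su2u2
        ), 4, 4)
        r <- c(Sy, Sxy, Syu1, Syu2)
        b <- tryCatch(solve(M, r), error = function(e) NULL)
        if (is.null(b)) next
        rss <- yy - sum(b * r)
        if (rss < best_rss - 1e-12 * max(yy, 1)) {
          best_rss <- rss
          best_pair <- c(k1, k2)
        }
      }
    }
    if (is.null(best_pair)) abort("2-breakpoint grid search found no admissible fit.")
    psi_best <- x[best_pair]
  }

  final <- lm.fit(segmented_design(x, psi_best), y)
  cf <- coef(final)
  cf[is.na(cf)] <- 0
  new_breakpoint_fit(
    n_breakpoints = n_bp, psi = psi_best,
    coefficients = setNames(cf, c("(Intercept)", "x", paste0("hinge", seq_len(n_bp)))),
    rss = sum(final$residuals^2), n_points = n,
    converged = TRUE, n_iter = NA_integer_, method = "grid",
    x_range = range(x)
  )
}

thin_indices <- function(idx, grid_size) {
  if (!is.finite(grid_size) || length(idx) <= grid_size) return(idx)
  unique(idx[round(seq(1, length(idx), length.out = grid_size))])
}

#' Select among 0/1/2-breakpoint fits by BIC
#'
#' `select_model()` picks the fit with the smallest
#' `BIC = n log(rss / n) + p log(n)` (with `p = 2 + 2 n_bp` parameters);
#' ties, and exact fits with `rss` below `1e-12` of the response variance,
#' resolve to the fewest breakpoints. `select_breakpoint_model()` is the
#' convenience wrapper that computes the grid fits itself.
#'
#' @param fits A list of `breakpoint_fit` objects computed on the same data.
#' @return The winning `breakpoint_fit`, with the full candidate list in
#'   attribute `"candidates"`.
#' @export
select_model <- function(fits) {
  if (!length(fits)) abort("`fits` must be a non-empty list of breakpoint fits.")
  if (!all(vapply(fits, inherits, logical(1), "breakpoint_fit"))) {
    abort("All elements of `fits` must be breakpoint_fit objects.")
  }
  n <- vapply(fits, `[[`, integer(1), "n_points")
  if (length(unique(n)) != 1) {
    abort("Fits were not computed on identical data (n_points differ).")
  }
  nbp <- vapply(fits, `[[`, integer(1), "n_breakpoints")
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  ord <- order(nbp)
  fits <- fits[ord]; nbp <- nbp[ord]; rss <- rss[ord]
  n <- n[1]
  # "exact" fits: rss negligible relative to the variance left by the
  # simplest candidate; the fewest breakpoints achieving it win outright
  exact <- rss <= 1e-12 * max(rss)
  best <- if (any(exact)) {
    which(exact)[1]
  } else {
    bic <- vapply(fits, `[[`, numeric(1), "bic")
    # order() put fewer breakpoints first, so ties resolve to the simpler model
    which.min(bic)
  }
  out <- fits[[best]]
  attr(out, "candidates") <- fits
  out
}

#' @rdname select_model
#' @inheritParams fit_segmented_grid
#' @param max_bp Largest number of breakpoints to consider (default 2).
#' @export
select_breakpoint_model <- function(x, y, max_bp = 2, min_seg = 5,
                                    grid_size = 80) {
  fits <- list(fit_line(x, y))
  for (k in seq_len(max_bp)) {
    n_needed <- (k + 1) * min_seg + 1
    if (length(x) >= n_needed) {
      fits[[k + 1]] <- fit_segmented_grid(
        x, y, n_bp = k, min_seg = min_seg,
        grid_size = if (k == 1) Inf else grid_size
      )
    }
  }
  select_model(fits)
}

#' @method tidy breakpoint_fit
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      term = "intercept", estimate = x$intercept, segment = NA_integer_
    ),
    tibble::tibble(
      term = paste0("slope", seq_along(x$slopes)),
      estimate = x$slopes,
      segment = seq_along(x$slopes)
    ),
    if (x$n_breakpoints > 0) tibble::tibble(
      term = paste0("psi", seq_along(x$psi)),
      estimate = x$psi,
      segment = NA_integer_
    )
  )
}

#' @method glance breakpoint_fit
#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    n_breakpoints = x$n_breakpoints,
    rss = x$rss,
    bic = x$bic,
    n_points = x$n_points,
    converged = x$converged,
    n_iter = x$n_iter,
    method = x$method
  )
}

check_xy <- function(x, y, min_n = 2) {
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric.")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n) {
    abort(sprintf("Need at least %d finite (x, y) pairs, got %d.",
                  min_n, length(x)))
  }
  ord <- order(x)
  list(x = x[ord], y = y[ord])
}
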