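#' Plateau (breakpoint) regression for the critical FTSW threshold
#'
#' Fits the continuous two-segment model that defines the critical fraction
#' of transpirable soil water, FTSWc: NTR holds at a plateau while
#' `ftsw >= c` and declines linearly below `c`. By default the declining
#' segment is constrained through the origin (`slope = plateau / c`),
#' matching the observation that transpiration falls linearly to zero in
#' dry soil; `free_slope = TRUE` relaxes the constraint for robustness
#' checks. The breakpoint is located by a grid search (candidate thresholds
#' must leave at least two points on each side), refined locally by
#' golden-section minimization, and its 95% confidence interval is obtained
#' by a seeded percentile bootstrap over response points.
#'
#' @param points data.frame with columns `ftsw` and `ntr`; rows flagged in
#'   an `excluded` column (if present) and non-finite rows are dropped
#'   before fitting.
#' @param free_slope Estimate the declining slope freely instead of
#'   constraining the segment through the origin.
#' @param fix_plateau Optional fixed plateau level (e.g. 1); `NULL`
#'   (default) estimates it.
#' @param grid Candidate breakpoints for the grid search
#'   (default `seq(0.02, 0.95, by = 0.005)`).
#' @param boot Number of bootstrap draws for the CI (default 500; 0 skips
#'   the bootstrap).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `plateau_fit`: list with `ftswc`, `plateau`,
#'   `slope` (decline per unit FTSW), `sse`, `ci95_ftswc`, `n_points`,
#'   `free_slope`, `converged`.
#' @seealso [grid_breakpoint_oracle()] for the brute-force check,
#'   [fit_logistic()] for the smooth alternative.
#' @export
fit_plateau <- function(points, free_slope = FALSE, fix_plateau = NULL,
                        grid = seq(0.02, 0.95, by = 0.005), boot = 500,
                        seed = 1) {
  pts <- clean_points(points)
  if (nrow(pts) < 6) {
    stop("plateau regression needs at least 6 response points", call. = FALSE)
  }
  fit <- plateau_core(pts$ftsw, pts$ntr, grid, free_slope, fix_plateau)
  flat_sse <- sum((pts$ntr - mean(pts$ntr))^2)
  if (flat_sse <= fit$sse * (1 + 1e-8) + 1e-12) {
    stop("no breakpoint: response shows no decline below any candidate ",
         "threshold", call. = FALSE)
  }
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    draws <- withr_seed(seed, {
      vapply(seq_len(boot), function(i) {
        idx <- sample.int(nrow(pts), replace = TRUE)
        out <- tryCatch(
          plateau_core(pts$ftsw[idx], pts$ntr[idx], grid, free_slope,
                       fix_plateau)$ftswc,
          error = function(e) NA_real_)
        out
      }, numeric(1))
    })
    draws <- draws[is.finite(draws)]
    if (length(draws) >= boot / 2) {
      q <- unname(stats::quantile(draws, c(0.025, 0.975), type = 7))
      ci <- c(min(q[1], fit$ftswc), max(q[2], fit$ftswc))
    }
  }
  structure(list(ftswc = fit$ftswc, plateau = fit$plateau,
                 slope = fit$slope, sse = fit$sse, ci95_ftswc = ci,
                 n_points = nrow(pts), free_slope = free_slope,
                 n_boot = if (boot > 0) boot else 0L, converged = TRUE),
            class = "plateau_fit")
}

# drop excluded/non-finite rows
clean_points <- function(points) {
  keep <- is.finite(points$ftsw) & is.finite(points$ntr)
  if (!is.null(points$excluded)) keep <- keep & !points$excluded
  points[keep, , drop = FALSE]
}

# segment-model SSE at one candidate breakpoint; closed-form profile over
# the linear parameters
plateau_sse <- function(ftsw, ntr, c0, free_slope, fix_plateau) {
  if (free_slope) {
    basis <- pmin(ftsw - c0, 0)
    if (is.null(fix_plateau)) {
      co <- stats::lm.fit(cbind(1, basis), ntr)
      list(sse = sum(co$residuals^2), plateau = unname(co$coefficients[1]),
           slope = unname(co$coefficients[2]))
    } else {
      y <- ntr - fix_plateau
      s <- sum(y * basis) / sum(basis^2)
      list(sse = sum((y - s * basis)^2), plateau = fix_plateau, slope = s)
    }
  } else {
    g <- pmin(1, ftsw / c0)
    p <- if (is.null(fix_plateau)) sum(ntr * g) / sum(g^2) else fix_plateau
    list(sse = sum((ntr - p * g)^2), plateau = p, slope = p / c0)
  }
}

plateau_core <- function(ftsw, ntr, grid, free_slope = FALSE,
                         fix_plateau = NULL) {
  grid <- sort(grid)
  n_below <- vapply(grid, function(c0) sum(ftsw < c0), 0L)
  admissible <- grid[n_below >= 2L & (length(ftsw) - n_below) >= 2L]
  if (!length(admissible)) {
    stop("no breakpoint: no candidate threshold leaves two points on ",
         "each side", call. = FALSE)
  }
  sse <- vapply(admissible,
                function(c0) plateau_sse(ftsw, ntr, c0, free_slope,
                                         fix_plateau)$sse,
                numeric(1))
  best <- which.min(sse)  # ties resolve toward the smaller threshold
  c_best <- admissible[best]
  if (c_best == admissible[length(admissible)] && length(admissible) > 1) {
    warning("breakpoint at the upper grid bound: the response may be ",
            "declining over its whole range", call. = FALSE)
  }
  # local refinement between the neighbouring grid points
  step <- if (length(grid) > 1) min(diff(grid)) else 0
  if (step > 0) {
    lo <- max(min(admissible), c_best - step)
    hi <- min(max(admissible), c_best + step)
    if (hi > lo) {
      op <- stats::optimize(function(c0) {
        plateau_sse(ftsw, ntr, c0, free_slope, fix_plateau)$sse
      }, interval = c(lo, hi))
      if (op$objective < sse[best]) c_best <- op$minimum
    }
  }
  out <- plateau_sse(ftsw, ntr, c_best, free_slope, fix_plateau)
  list(ftswc = c_best, plateau = out$plateau, slope = out$slope,
       sse = out$sse)
}

#' Brute-force grid oracle for the breakpoint
#'
#' Exhaustive SSE minimization of the same two-segment model over a finite
#' grid of candidate breakpoints, with ties broken toward the smaller
#' threshold. Independent of [fit_plateau()]'s search-and-refine path: each
#' candidate is evaluated by an ordinary [stats::lm()] on the segment
#' basis. `fit_plateau()`'s SSE can never exceed the oracle's on the same
#' grid.
#'
#' @param points data.frame with `ftsw`, `ntr`.
#' @param c_grid Finite vector of candidate breakpoints.
#' @param free_slope Same meaning as in [fit_plateau()].
#' @return list with `c_star` and `sse_star`.
#' @export
grid_breakpoint_oracle <- function(points, c_grid, free_slope = FALSE) {
  pts <- clean_points(points)
  c_grid <- sort(c_grid)
  below <- vapply(c_grid, function(c0) sum(pts$ftsw < c0), 0L)
  c_grid <- c_grid[below >= 2L & (nrow(pts) - below) >= 2L]
  if (!length(c_grid)) stop("no candidate with two points on each side",
                            call. = FALSE)
  sse <- vapply(c_grid, function(c0) {
    x <- if (free_slope) pmin(pts$ftsw - c0, 0) else pmin(1, pts$ftsw / c0)
    fm <- if (free_slope) stats::lm(pts$ntr ~ x) else stats::lm(pts$ntr ~ x - 1)
    sum(stats::residuals(fm)^2)
  }, numeric(1))
  best <- which.min(sse)  # which.min takes the first = smallest c on ties
  list(c_star = c_grid[best], sse_star = sse[best])
}

#' Logistic NTR-FTSW response curve
#'
#' Fits `NTR = 1 / (1 + A * exp(B * FTSW))` by nonlinear least squares.
#' `A` and `B` are empirical shape coefficients (`B < 0` for a response
#' that rises with soil water); cultivars are compared through the 95%
#' confidence intervals of the two coefficients. Starting values come from
#' the log-linearization `log(1/NTR - 1) = log(A) + B * FTSW`, with a fixed
#' multi-start fallback grid (`A` in 10/50/200, `B` in -5/-15/-30);
#' non-convergence from every start yields a flagged fit, never a silent
#' fallback.
#'
#' @param points data.frame with `ftsw`, `ntr` (>= 5 points spanning an
#'   FTSW range of at least 0.3).
#' @return Object of class `logistic_fit`: `A`, `B`, `ci95_A`, `ci95_B`,
#'   `sse`, `n_points`, `converged`, `message`.
#' @export
fit_logistic <- function(points) {
  pts <- clean_points(points)
  if (nrow(pts) < 5) {
    stop("logistic fit needs at least 5 response points", call. = FALSE)
  }
  if (diff(range(pts$ftsw)) < 0.3) {
    stop("response points must span an FTSW range of at least 0.3",
         call. = FALSE)
  }
  dat <- data.frame(f = pts$ftsw, y = pts$ntr)
  z <- log(1 / pmin(pmax(dat$y, 1e-6), 1 - 1e-6) - 1)
  lin <- stats::lm(z ~ dat$f)
  starts <- rbind(
    c(A = exp(unname(stats::coef(lin)[1])), B = unname(stats::coef(lin)[2])),
    as.matrix(expand.grid(A = c(10, 50, 200), B = c(-5, -15, -30))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(A = unname(max(starts[i, "A"], 1e-6)),
               B = unname(starts[i, "B"]))
    fm <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + A * exp(B * f)), data = dat,
                        start = st, control = minpack.lm::nls.lm.control(
                          maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fm)) {
      fm <- tryCatch(
        stats::nls(y ~ 1 / (1 + A * exp(B * f)), data = dat, start = st,
                   algorithm = "port", lower = c(A = 1e-9, B = -Inf),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = FALSE)),
        error = function(e) NULL)
    }
    if (!is.null(fm)) {
      rss <- sum(stats::residuals(fm)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fm = fm, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(A = NA_real_, B = NA_real_,
                          ci95_A = c(NA_real_, NA_real_),
                          ci95_B = c(NA_real_, NA_real_), sse = NA_real_,
                          n_points = nrow(pts), converged = FALSE,
                          message = "no start converged"),
                     class = "logistic_fit"))
  }
  co <- summary(best$fm)$coefficients
  tq <- stats::qt(0.975, df = nrow(pts) - 2)
  structure(list(A = co["A", "Estimate"], B = co["B", "Estimate"],
                 ci95_A = co["A", "Estimate"] +
                   c(-1, 1) * tq * co["A", "Std. Error"],
                 ci95_B = co["B", "Estimate"] +
                   c(-1, 1) * tq * co["B", "Std. Error"],
                 sse = best$rss, n_points = nrow(pts), converged = TRUE,
                 message = "converged"),
            class = "logistic_fit")
}

#' Compare two cultivars' logistic response curves
#'
#' Two response curves are called distinct when the 95% confidence
#' intervals of either coefficient (`A` or `B`) fail to overlap. Flagged
#' (non-converged) fits give an `"undetermined"` verdict.
#'
#' @param fit1,fit2 Objects from [fit_logistic()].
#' @return list with logicals `overlap_A`, `overlap_B` and a `verdict` of
#'   `"distinct"`, `"not distinct"` or `"undetermined"`.
#' @export
compare_cultivar_curves <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "logistic_fit"), inherits(fit2, "logistic_fit"))
  if (!isTRUE(fit1$converged) || !isTRUE(fit2$converged)) {
    return(list(overlap_A = NA, overlap_B = NA, verdict = "undetermined"))
  }
  overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  oa <- overlaps(fit1$ci95_A, fit2$ci95_A)
  ob <- overlaps(fit1$ci95_B, fit2$ci95_B)
  list(overlap_A = oa, overlap_B = ob,
       verdict = if (oa && ob) "not distinct" else "distinct")
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat("Plateau regression fit\n")
  cat(sprintf("  FTSWc: %.4f  [95%% CI %.4f, %.4f; %d bootstrap draws]\n",
              x$ftswc, x$ci95_ftswc[1], x$ci95_ftswc[2], x$n_boot))
  cat(sprintf("  plateau: %.4f   slope below threshold: %.4f per FTSW\n",
              x$plateau, x$slope))
  cat(sprintf("  SSE: %.6g on %d points (%s slope)\n", x$sse, x$n_points,
              if (x$free_slope) "free" else "through-origin"))
  invisible(x)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic NTR-FTSW fit: NTR = 1 / (1 + A exp(B FTSW))\n")
  if (isTRUE(x$converged)) {
    cat(sprintf("  A: %.4g  [%.4g, %.4g]\n", x$A, x$ci95_A[1], x$ci95_A[2]))
    cat(sprintf("  B: %.4g  [%.4g, %.4g]\n", x$B, x$ci95_B[1], x$ci95_B[2]))
    cat(sprintf("  SSE: %.6g on %d points\n", x$sse, x$n_points))
  } else {
    cat("  fit did not converge:", x$message, "\n")
  }
  invisible(x)
}

#' Fit FTSWc for every cultivar in a response-point table
#'
#' Convenience wrapper: splits a [build_response_points()] table by
#' cultivar, fits the plateau regression (and optionally the logistic
#' curve) per cultivar, and returns one row per cultivar in the results
#' schema. Cultivars whose fit fails are reported with `converged = FALSE`
#' and the error message, never dropped silently.
#'
#' @param points Response-point table from [build_response_points()].
#' @param boot,free_slope,fix_plateau,grid Passed to [fit_plateau()].
#' @param logistic Also fit the logistic curve per cultivar (default TRUE).
#' @param seed Base seed; each cultivar's bootstrap gets its own stream.
#' @return data.frame `cultivar, n_points, A, A_lo, A_hi, B, B_lo, B_hi,
#'   ftswc, ftswc_lo, ftswc_hi, plateau, slope, sse, converged`.
#' @export
fit_all_cultivars <- function(points, boot = 500, free_slope = FALSE,
                              fix_plateau = NULL,
                              grid = seq(0.02, 0.95, by = 0.005),
                              logistic = TRUE, seed = 1) {
  cvs <- sort(unique(points$cultivar))
  rows <- lapply(seq_along(cvs), function(i) {
    pts <- points[points$cultivar == cvs[i], , drop = FALSE]
    row <- data.frame(cultivar = cvs[i], n_points = nrow(clean_points(pts)),
                      A = NA_real_, A_lo = NA_real_, A_hi = NA_real_,
                      B = NA_real_, B_lo = NA_real_, B_hi = NA_real_,
                      ftswc = NA_real_, ftswc_lo = NA_real_,
                      ftswc_hi = NA_real_, plateau = NA_real_,
                      slope = NA_real_, sse = NA_real_, converged = FALSE,
                      message = "", stringsAsFactors = FALSE)
    pf <- tryCatch(fit_plateau(pts, free_slope = free_slope,
                               fix_plateau = fix_plateau, grid = grid,
                               boot = boot, seed = pot_seed(seed, i)),
                   error = function(e) e)
    if (inherits(pf, "error")) {
      row$message <- conditionMessage(pf)
      return(row)
    }
    row[c("ftswc", "ftswc_lo", "ftswc_hi", "plateau", "slope", "sse")] <-
      c(pf$ftswc, pf$ci95_ftswc, pf$plateau, pf$slope, pf$sse)
    row$converged <- TRUE
    if (logistic) {
      lf <- tryCatch(fit_logistic(pts), error = function(e) NULL)
      if (!is.null(lf) && isTRUE(lf$converged)) {
        row[c("A", "A_lo", "A_hi", "B", "B_lo", "B_hi")] <-
          c(lf$A, lf$ci95_A, lf$B, lf$ci95_B)
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
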