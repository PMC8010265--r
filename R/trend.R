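#' Mean FTSWc per decade of cultivar release
#'
#' Averages the defined critical thresholds within each release decade.
#' Missing thresholds (cultivars whose dry-down never yielded a fit) are
#' excluded, never imputed; a decade with no defined value is dropped with
#' a warning.
#'
#' @param table data.frame with columns `decade` and `ftswc` — either the
#'   packaged reference table ([load_table1_fixture()]) or a per-cultivar
#'   results table joined to release decades.
#' @return data.frame of class `decade_series`: `decade`, `mean_ftswc`,
#'   `n` (cultivars contributing), ordered by decade.
#' @export
decade_means <- function(table) {
  stopifnot(all(c("decade", "ftswc") %in% names(table)))
  ok <- table[is.finite(table$ftswc), c("decade", "ftswc")]
  dropped <- setdiff(unique(table$decade), unique(ok$decade))
  if (length(dropped)) {
    warning("decade(s) with no defined FTSWc excluded: ",
            paste(sort(dropped), collapse = ", "), call. = FALSE)
  }
  if (!nrow(ok)) stop("no defined FTSWc values", call. = FALSE)
  agg <- stats::aggregate(ftswc ~ decade, data = ok, FUN = mean)
  names(agg)[2] <- "mean_ftswc"
  agg$n <- stats::aggregate(ftswc ~ decade, data = ok, FUN = length)$ftswc
  agg <- agg[order(agg$decade), ]
  rownames(agg) <- NULL
  class(agg) <- c("decade_series", "data.frame")
  agg
}

#' Knotted linear-spline trend of FTSWc across decades
#'
#' Ordinary least squares on the hinge basis
#' `mean_ftswc = a + b * Time + c * max(0, Time - knot_index)`, where
#' `Time = (decade - 1915) / 10` counts decades (so slopes are per decade)
#' and the knot sits at 1965, midway between the 1960 and 1970 design
#' points. `b` is the pre-knot slope, `b + c` the post-knot slope (standard
#' error propagated from the coefficient covariance), and the p-value of
#' `c` tests whether the trend changes at the knot. Two-sided t-tests use
#' `n - 3` degrees of freedom.
#'
#' @param series A [decade_means()] table (or any data.frame with `decade`
#'   and `mean_ftswc`).
#' @param knot_year Knot position in calendar years (default 1965).
#' @param weighted Weight decades by their cultivar count `n`
#'   (default FALSE: the trend of the decade averages themselves).
#' @return Object of class `spline_trend_fit`: `a`, `b`, `c`, `knot_year`,
#'   `se_a`, `se_b`, `se_c`, `p_b`, `p_c`, `b_plus_c`, `se_b_plus_c`,
#'   `p_b_plus_c`, `r2`, `n_decades`, plus the underlying `lm` fit.
#' @export
fit_spline_trend <- function(series, knot_year = 1965, weighted = FALSE) {
  stopifnot(all(c("decade", "mean_ftswc") %in% names(series)))
  if (nrow(series) < 4) {
    stop("spline trend needs at least 4 decades", call. = FALSE)
  }
  time <- (series$decade - 1915) / 10
  knot <- (knot_year - 1915) / 10
  if (sum(time < knot) < 2 || sum(time > knot) < 2) {
    stop("need at least 2 decades on each side of the knot", call. = FALSE)
  }
  hinge <- pmax(0, time - knot)
  dat <- data.frame(y = series$mean_ftswc, time = time, hinge = hinge)
  w <- if (weighted) {
    if (is.null(series$n)) stop("`weighted = TRUE` needs an `n` column",
                                call. = FALSE)
    series$n
  }
  fm <- stats::lm(y ~ time + hinge, data = dat, weights = w)
  if (fm$rank < 3) {
    stop("rank-deficient design: decades do not identify both slopes",
         call. = FALSE)
  }
  sm <- suppressWarnings(summary(fm))  # zero-residual fits warn in summary.lm
  co <- sm$coefficients
  V <- suppressWarnings(stats::vcov(fm))
  bpc <- co["time", "Estimate"] + co["hinge", "Estimate"]
  se_bpc <- sqrt(V["time", "time"] + V["hinge", "hinge"] +
                   2 * V["time", "hinge"])
  df <- nrow(series) - 3
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant series: no variance to explain
  structure(list(
    a = co["(Intercept)", "Estimate"], b = co["time", "Estimate"],
    c = co["hinge", "Estimate"], knot_year = knot_year,
    se_a = co["(Intercept)", "Std. Error"], se_b = co["time", "Std. Error"],
    se_c = co["hinge", "Std. Error"],
    p_b = co["time", "Pr(>|t|)"], p_c = co["hinge", "Pr(>|t|)"],
    b_plus_c = bpc, se_b_plus_c = se_bpc,
    p_b_plus_c = 2 * stats::pt(abs(bpc / se_bpc), df = df,
                               lower.tail = FALSE),
    r2 = r2, n_decades = nrow(series), lm = fm),
    class = "spline_trend_fit")
}

#' Post-knot slope of the decade trend
#'
#' The decline rate per decade after the knot is the sum `b + c`; its
#' standard error comes from the coefficient covariance and its p-value
#' from a two-sided t-test on `n - 3` degrees of freedom.
#'
#' @param fit A [fit_spline_trend()] object.
#' @return Named numeric vector `estimate`, `se`, `p`.
#' @export
slope_after_knot <- function(fit) {
  stopifnot(inherits(fit, "spline_trend_fit"))
  c(estimate = fit$b_plus_c, se = fit$se_b_plus_c, p = fit$p_b_plus_c)
}

#' @export
print.spline_trend_fit <- function(x, ...) {
  cat(sprintf("Linear-spline trend, knot at %d (%d decades)\n",
              x$knot_year, x$n_decades))
  cat(sprintf("  pre-knot slope  b   : %+.4f per decade (SE %.4f, p = %.3g)\n",
              x$b, x$se_b, x$p_b))
  cat(sprintf("  post-knot slope b+c : %+.4f per decade (SE %.4f, p = %.3g)\n",
              x$b_plus_c, x$se_b_plus_c, x$p_b_plus_c))
  cat(sprintf("  slope change    c   : %+.4f (SE %.4f, p = %.3g)\n",
              x$c, x$se_c, x$p_c))
  cat(sprintf("  r-squared: %.3f\n", x$r2))
  invisible(x)
}

#' Write the trend report CSV
#'
#' @param fit A [fit_spline_trend()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(fit, path) {
  df <- data.frame(a = fit$a, b = fit$b, se_b = fit$se_b, p_b = fit$p_b,
                   c = fit$c, se_c = fit$se_c, p_c = fit$p_c,
                   b_plus_c = fit$b_plus_c, se_bpc = fit$se_b_plus_c,
                   p_bpc = fit$p_b_plus_c, r2 = fit$r2,
                   knot_year = fit$knot_year, n_decades = fit$n_decades)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
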