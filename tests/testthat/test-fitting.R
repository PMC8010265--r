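test_that("plateau regression inverts exact two-segment data", {
  cases <- list(list(ftswc = 0.30, plateau = 1),
                list(ftswc = 0.45, plateau = 0.9),
                list(ftswc = 0.20, plateau = 1.1))
  for (cs in cases) {
    fit <- fit_plateau(piecewise_points(cs$ftswc, cs$plateau), boot = 0)
    expect_equal(fit$ftswc, cs$ftswc, tolerance = 1e-6)
    expect_equal(fit$plateau, cs$plateau, tolerance = 1e-6)
    expect_equal(fit$slope, cs$plateau / cs$ftswc, tolerance = 1e-5)
    expect_lt(fit$sse, 1e-12)
  }
})

test_that("plateau regression preconditions and degenerate shapes error", {
  expect_error(fit_plateau(data.frame(ftsw = c(0.1, 0.5, 0.9),
                                      ntr = c(0.3, 1, 1))), "at least 6")
  flat <- data.frame(ftsw = seq(0.3, 1, by = 0.1), ntr = rep(1, 8))
  expect_error(fit_plateau(flat, boot = 0), "no breakpoint")
  declining <- data.frame(ftsw = seq(0.05, 0.6, by = 0.05))
  declining$ntr <- declining$ftsw / 0.9
  expect_warning(fit_plateau(declining, boot = 0, free_slope = TRUE),
                 "upper grid bound")
})

test_that("noisy plateau fit recovers the threshold and bootstrap CI covers it", {
  set.seed(77)
  f <- rep(seq(0.025, 1, by = 0.025), 2)
  pts <- data.frame(ftsw = f,
                    ntr = pmin(1, f / 0.35) + rnorm(length(f), sd = 0.05))
  fit <- fit_plateau(pts, boot = 500, seed = 5)
  expect_lt(abs(fit$ftswc - 0.35), 0.05)
  expect_true(fit$ci95_ftswc[1] <= 0.35 && 0.35 <= fit$ci95_ftswc[2])
  expect_true(fit$ci95_ftswc[1] <= fit$ftswc & fit$ftswc <= fit$ci95_ftswc[2])
})

test_that("grid oracle ties break toward the smaller threshold", {
  # symmetric pair of points around two equally good candidates
  pts <- data.frame(ftsw = c(0, 0, 0.5, 0.6, 0.8, 1),
                    ntr = c(0, 0, 1, 1, 1, 1))
  or <- grid_breakpoint_oracle(pts, c(0.2, 0.4))
  expect_equal(or$c_star, 0.2)
  expect_equal(or$sse_star, 0)
})

test_that("fit_plateau SSE never exceeds the grid oracle SSE", {
  set.seed(13)
  grid <- seq(0.02, 0.95, by = 0.005)
  for (i in 1:25) {
    n <- sample(12:40, 1)
    cc <- runif(1, 0.1, 0.6)
    pts <- data.frame(ftsw = runif(n))
    pts$ntr <- pmin(1, pts$ftsw / cc) + rnorm(n, sd = 0.05)
    fit <- tryCatch(fit_plateau(pts, grid = grid, boot = 0),
                    error = function(e) NULL)
    if (is.null(fit)) next
    oracle <- grid_breakpoint_oracle(pts, grid)
    expect_lte(fit$sse, oracle$sse_star + 1e-9)
  }
})

test_that("scaling NTR rescales plateau and slope but not the threshold", {
  set.seed(3)
  f <- seq(0.02, 1, by = 0.02)
  pts <- data.frame(ftsw = f, ntr = pmin(1, f / 0.3) + rnorm(length(f), 0.02))
  base <- fit_plateau(pts, free_slope = TRUE, boot = 0)
  scaled <- fit_plateau(transform(pts, ntr = 3 * ntr), free_slope = TRUE,
                        boot = 0)
  expect_equal(scaled$ftswc, base$ftswc, tolerance = 1e-6)
  expect_equal(scaled$plateau, 3 * base$plateau, tolerance = 1e-6)
  expect_equal(scaled$slope, 3 * base$slope, tolerance = 1e-6)
})

test_that("logistic fit recovers exact coefficients and respects preconditions", {
  f <- seq(0.02, 1, by = 0.02)
  pts <- data.frame(ftsw = f, ntr = 1 / (1 + 50 * exp(-15 * f)))
  fit <- fit_logistic(pts)
  expect_true(fit$converged)
  expect_lt(abs(fit$A - 50) / 50, 1e-4)
  expect_lt(abs(fit$B + 15) / 15, 1e-4)
  expect_error(fit_logistic(pts[1:3, ]), "at least 5")
  narrow <- data.frame(ftsw = seq(0.4, 0.6, by = 0.04), ntr = runif(6))
  expect_error(fit_logistic(narrow), "range")
})

test_that("logistic confidence intervals cover the truth in repeated noisy fits", {
  f <- seq(0.02, 1, by = 0.02)
  mu <- 1 / (1 + 50 * exp(-15 * f))
  set.seed(42)
  covered <- replicate(100, {
    fit <- fit_logistic(data.frame(ftsw = f,
                                   ntr = mu + rnorm(length(f), sd = 0.05)))
    fit$ci95_A[1] <= 50 && 50 <= fit$ci95_A[2] &&
      fit$ci95_B[1] <= -15 && -15 <= fit$ci95_B[2]
  })
  expect_gte(mean(covered), 0.9)
})

test_that("logistic half-maximum lies below the plateau breakpoint", {
  fit <- fit_logistic(piecewise_points(0.3, step = 0.02))
  half_max <- log(fit$A) / -fit$B
  expect_gt(half_max, 0)
  expect_lt(half_max, 0.3)
})

test_that("curve comparison follows the CI overlap rule", {
  mk <- function(ciA, ciB) structure(list(A = mean(ciA), B = mean(ciB),
                                          ci95_A = ciA, ci95_B = ciB,
                                          converged = TRUE),
                                     class = "logistic_fit")
  same <- mk(c(10, 20), c(-16, -14))
  expect_identical(compare_cultivar_curves(same, same)$verdict, "not distinct")
  expect_identical(compare_cultivar_curves(mk(c(10, 20), c(-16, -14)),
                                           mk(c(30, 40), c(-16, -14)))$verdict,
                   "distinct")
  expect_identical(compare_cultivar_curves(mk(c(10, 30), c(-16, -14)),
                                           mk(c(25, 40), c(-15, -13)))$verdict,
                   "not distinct")
  bad <- mk(c(1, 2), c(-2, -1)); bad$converged <- FALSE
  expect_identical(compare_cultivar_curves(bad, same)$verdict, "undetermined")
})

test_that("per-cultivar wrapper reports failures without dropping cultivars", {
  ds <- tiny_experiment(ftswc = c(0.2, 0.4))
  pts <- build_response_points(ds)
  flat <- data.frame(cultivar = "FLAT", replicate = 1L, day = 2:9,
                     ftsw = seq(0.3, 1, by = 0.1), ntr = 1,
                     excluded = FALSE, reason = "")
  res <- fit_all_cultivars(rbind(pts, flat), boot = 50, seed = 2)
  expect_identical(res$cultivar, c("CV01", "CV02", "FLAT"))
  expect_identical(res$converged, c(TRUE, TRUE, FALSE))
  expect_match(res$message[3], "no breakpoint|two points")
  expect_equal(res$ftswc[1:2], c(0.2, 0.4), tolerance = 0.02)
})
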