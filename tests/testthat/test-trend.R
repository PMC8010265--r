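test_that("decade means average defined thresholds and report counts", {
  t1 <- load_table1_fixture()
  dm <- decade_means(t1)
  expect_equal(dm$mean_ftswc[dm$decade == 1920], 0.23)
  # hand mean over the four defined 1950s thresholds
  expect_equal(dm$mean_ftswc[dm$decade == 1950],
               mean(c(0.36, 0.28, 0.33, 0.42)))
  expect_identical(dm$n[dm$decade == 1950], 4L)
  expect_identical(sum(dm$n), 59L)
  # a decade whose every threshold is missing is excluded with a warning
  toy <- data.frame(decade = c(1920, 1920, 1930), ftswc = c(0.2, 0.3, NA))
  expect_warning(dm2 <- decade_means(toy), "1930")
  expect_identical(dm2$decade, 1920)
  expect_equal(dm2$mean_ftswc, 0.25)
})

test_that("spline trend recovers exact piecewise slopes with r2 = 1", {
  decades <- seq(1920, 2010, by = 10)
  time <- (decades - 1915) / 10
  tent <- 0.20 + 0.03 * pmin(time, 5) - 0.03 * pmax(0, time - 5)
  fit <- fit_spline_trend(data.frame(decade = decades, mean_ftswc = tent))
  expect_equal(fit$a, 0.20, tolerance = 1e-10)
  expect_equal(fit$b, 0.03, tolerance = 1e-10)
  expect_equal(fit$b_plus_c, -0.03, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(sum(residuals(fit$lm)^2), 1e-20)
  # symmetric tent: post-knot slope is minus the pre-knot slope
  sk <- slope_after_knot(fit)
  expect_equal(unname(sk["estimate"]), -0.03, tolerance = 1e-10)
})

test_that("flat and knot-free series give degenerate but defined fits", {
  decades <- seq(1920, 2010, by = 10)
  flat <- fit_spline_trend(data.frame(decade = decades,
                                      mean_ftswc = rep(0.3, 10)))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$c, 0, tolerance = 1e-12)
  expect_identical(flat$r2, 0)
  # c = 0: the post-knot slope reduces to b with b's standard error
  line <- fit_spline_trend(data.frame(decade = decades,
                                      mean_ftswc = 0.2 + 0.005 * seq(0, 9)))
  expect_equal(line$b_plus_c, line$b, tolerance = 1e-9)
})

test_that("trend is equivariant under value shifts", {
  set.seed(8)
  decades <- seq(1920, 2010, by = 10)
  y <- 0.3 + cumsum(rnorm(10, sd = 0.02))
  f1 <- fit_spline_trend(data.frame(decade = decades, mean_ftswc = y))
  f2 <- fit_spline_trend(data.frame(decade = decades, mean_ftswc = y + 0.1))
  expect_equal(f2$a, f1$a + 0.1)
  expect_equal(f2$b, f1$b)
  expect_equal(f2$c, f1$c)
  expect_equal(f2$r2, f1$r2)
})

test_that("trend preconditions are enforced", {
  few <- data.frame(decade = c(1920, 1930, 1940), mean_ftswc = c(.2, .3, .25))
  expect_error(fit_spline_trend(few), "at least 4")
  onesided <- data.frame(decade = c(1970, 1980, 1990, 2000),
                         mean_ftswc = c(.2, .3, .25, .2))
  expect_error(fit_spline_trend(onesided), "each side")
})

test_that("weighted trend uses cultivar counts and the report CSV round-trips", {
  dm <- decade_means(load_table1_fixture())
  fw <- fit_spline_trend(dm, weighted = TRUE)
  fu <- fit_spline_trend(dm)
  expect_false(isTRUE(all.equal(fw$b, fu$b)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trend_csv(fu, path)
  back <- read.csv(path)
  expect_equal(back$b, fu$b, tolerance = 1e-10)
  expect_equal(back$b_plus_c, fu$b_plus_c, tolerance = 1e-10)
  expect_identical(back$n_decades, 10L)
})
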