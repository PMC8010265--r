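test_that("two-segment response function is continuous, clamped and exact", {
  expect_identical(response_function(0.5, 0.3), 1)
  expect_identical(response_function(0.15, 0.3), 0.5)
  expect_identical(response_function(0, 0.3), 0)
  # continuity at the threshold
  eps <- 1e-9
  expect_equal(response_function(0.3 - eps, 0.3), response_function(0.3, 0.3),
               tolerance = 1e-7)
  expect_error(response_function(1.2, 0.3), "\\[0, 1\\]")
  expect_error(response_function(0.5, 1.5), "\\(0, 1\\)")
})

test_that("bare and evaporation-only pots follow the stated limits", {
  des <- drydown_design(n_days = 5, evap_g_day = 10, seed = 1)
  bare <- simulate_pot_series(NULL, des, "bare")
  expect_equal(diff(bare$weight_g), rep(-10, 4))
  # evaporation-only limit: a "plant" that never transpires but grows
  prof <- data.frame(name = "x", ftswc_true = 0.3, plateau_true = 1,
                     t_pot_g = 0, growth_g_day = 2)
  dr <- simulate_pot_series(prof, des, "drought")
  expect_equal(diff(dr$weight_g), rep(-10 + 2, 4))
})

test_that("simulated experiments have the designed shape and determinism", {
  profiles <- cultivar_profiles(sprintf("C%02d", 1:80),
                                ftswc_true = seq(0.1, 0.5, length.out = 80))
  des <- drydown_design(n_days = 14, n_reps = 2, n_bare = 10,
                        noise_sd_g = 2, seed = 9)
  ds <- simulate_experiment(profiles, des)
  expect_identical(nrow(ds), 14L * (2L * 2L * 80L + 10L))
  expect_identical(ds, simulate_experiment(profiles, des))
  des2 <- drydown_design(n_days = 14, n_reps = 2, n_bare = 10,
                         noise_sd_g = 2, seed = 10)
  ds2 <- simulate_experiment(profiles, des2)
  expect_false(identical(ds$weight_g, ds2$weight_g))
  expect_error(simulate_experiment(profiles[0, ], des), "non-empty")
})

test_that("noiseless water balance is exact and ground-truth FTSW monotone", {
  ds <- tiny_experiment(ftswc = c(0.12, 0.3, 0.5))
  pot_truth <- attr(ds, "pot_truth")
  for (pot in split(ds, ds$pot_id)) {
    tr <- pot_truth[[pot$pot_id[1]]]
    loss <- if (pot$treatment[1] == "irrigated") {
      # recorded weights are pre-rewatering: losses accrue against the
      # refilled (day-1) weight, not the previous day's reading
      (pot$weight_g[1] - pot$weight_g)[-1]
    } else {
      pot$weight_g[-nrow(pot)] - pot$weight_g[-1]
    }
    expect_equal(loss, (tr$transp_g + tr$evap_g)[-1], tolerance = 1e-12)
    if (pot$treatment[1] == "drought") {
      expect_true(all(diff(tr$ftsw_true) <= 1e-12))
    }
  }
})

test_that("drought pots never transpire above demand while well-watered", {
  ds <- tiny_experiment(ftswc = 0.3)
  tr <- attr(ds, "pot_truth")[["P001"]]
  above <- tr$ftsw_true >= 0.3 & tr$day > 1
  expect_equal(tr$transp_g[above], rep(64, sum(above)))
})

test_that("VPD-scaled demand follows the supplied weather", {
  wx <- data.frame(day = 1:10, vpd_kpa = seq(0.8, 1.7, by = 0.1))
  des <- drydown_design(n_days = 10, weather = wx)
  expect_equal(des$demand_mult, wx$vpd_kpa / mean(wx$vpd_kpa))
  prof <- cultivar_profiles("x", ftswc_true = 0.3)
  irr <- simulate_pot_series(prof[1, ], des, "irrigated")
  loss <- irr$weight_g[1] - irr$weight_g[-1]
  expect_equal(loss, (10 + 64 * des$demand_mult)[-1])
})

test_that("truth sidecar CSV round-trips the ground-truth table", {
  ds <- tiny_experiment()
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(ds, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back, as.data.frame(attr(ds, "truth")),
               ignore_attr = TRUE, tolerance = 1e-12)
})
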