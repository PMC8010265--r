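#' Two-segment transpiration response to soil drying
#'
#' The generating model for a dry-down: relative transpiration holds at a
#' plateau while the fraction of transpirable soil water (FTSW) is above a
#' critical threshold, then declines linearly through the origin below it.
#' The curve is continuous at the threshold and exactly zero in dry soil.
#'
#' @param ftsw FTSW, a fraction in `[0, 1]` (vectorized).
#' @param ftswc Critical threshold, strictly inside `(0, 1)`.
#' @param plateau Plateau level of relative transpiration (default 1).
#' @return Relative transpiration: `plateau` for `ftsw >= ftswc`, else
#'   `plateau * ftsw / ftswc`.
#' @examples
#' response_function(0.5, 0.3)   # 1
#' response_function(0.15, 0.3)  # 0.5
#' @export
response_function <- function(ftsw, ftswc, plateau = 1) {
  if (any(ftsw < 0 | ftsw > 1)) {
    stop("`ftsw` must lie in [0, 1]", call. = FALSE)
  }
  if (length(ftswc) != 1 || ftswc <= 0 || ftswc >= 1) {
    stop("`ftswc` must be a single value in (0, 1)", call. = FALSE)
  }
  plateau * pmin(1, ftsw / ftswc)
}

#' Cultivar ground-truth profiles for the simulator
#'
#' Builds the per-cultivar parameter table the dry-down simulator consumes:
#' the true critical FTSW threshold, the well-watered relative-transpiration
#' plateau, the potential daily transpiration at full water, and an optional
#' daily fresh-mass growth term (a deliberate weight confound, off by
#' default because raw pot weights are not growth-corrected downstream).
#'
#' @param name Character vector of cultivar identifiers.
#' @param ftswc_true True thresholds in `[0.05, 0.8]` (recycled).
#' @param decade Release decade (year, e.g. 1970); carried metadata.
#' @param leaf_size One of `"small"`, `"medium"`, `"large"`; carried metadata.
#' @param plateau_true Well-watered plateau, dimensionless (default 1).
#' @param t_pot_g Potential transpiration at full water, g/day (default 64).
#' @param growth_g_day Daily fresh-mass gain, g/day (default 0).
#' @return A data.frame of class `cultivar_profiles`.
#' @export
cultivar_profiles <- function(name, ftswc_true, decade = 2000L,
                              leaf_size = "medium", plateau_true = 1,
                              t_pot_g = 64, growth_g_day = 0) {
  p <- data.frame(name = as.character(name), decade = as.integer(decade),
                  leaf_size = leaf_size, ftswc_true = ftswc_true,
                  plateau_true = plateau_true, t_pot_g = t_pot_g,
                  growth_g_day = growth_g_day, stringsAsFactors = FALSE)
  if (anyDuplicated(p$name)) stop("cultivar names must be unique", call. = FALSE)
  if (any(p$ftswc_true < 0.05 | p$ftswc_true > 0.8)) {
    stop("`ftswc_true` must lie in [0.05, 0.8]", call. = FALSE)
  }
  if (any(p$t_pot_g <= 0)) stop("`t_pot_g` must be positive", call. = FALSE)
  if (!all(p$leaf_size %in% c("small", "medium", "large"))) {
    stop("`leaf_size` must be small, medium or large", call. = FALSE)
  }
  class(p) <- c("cultivar_profiles", "data.frame")
  p
}

#' Draw a random panel of cultivar profiles
#'
#' Thresholds are drawn uniformly over `ftswc_range`, spanning the band
#' where dry-down studies across species typically locate the onset of
#' stomatal closure.
#'
#' @param n Number of cultivars.
#' @param seed RNG seed for the draw.
#' @param ftswc_range Range of true thresholds (default `c(0.1, 0.5)`).
#' @inheritParams cultivar_profiles
#' @return A `cultivar_profiles` data.frame with names `CV01`, `CV02`, ...
#' @export
sample_cultivar_profiles <- function(n, seed, ftswc_range = c(0.1, 0.5),
                                     plateau_true = 1, t_pot_g = 64,
                                     growth_g_day = 0) {
  stopifnot(n >= 1)
  cs <- withr_seed(seed, stats::runif(n, ftswc_range[1], ftswc_range[2]))
  cultivar_profiles(sprintf("CV%02d", seq_len(n)), ftswc_true = cs,
                    plateau_true = plateau_true, t_pot_g = t_pot_g,
                    growth_g_day = growth_g_day)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Dry-down experiment design
#'
#' Collects the physical and sampling parameters of one glasshouse
#' dry-down trial: two treatments (drought and rewatered irrigated
#' controls) replicated per cultivar, plus bare pots that measure soil
#' surface evaporation. Defaults describe a 4 L pot experiment: saturated
#' pot weight 5000 g of which 800 g is transpirable water, 10 g/day
#' bare-soil evaporation, and a 19-day trial.
#'
#' @param n_days Trial length in days (first weighing = day 1).
#' @param n_reps Technical replicates per cultivar x treatment.
#' @param n_bare Number of bare evaporation pots.
#' @param pot_capacity_g Saturated pot weight, g.
#' @param transpirable_g Total transpirable water per pot, g.
#' @param evap_g_day Daily bare-pot evaporation, g/day.
#' @param noise_sd_g Weighing (observation) noise s.d., g; added to the
#'   reported weights only, never to the underlying water balance.
#' @param seed Base RNG seed; each pot gets its own stream derived from
#'   `(seed, pot index)` so row order never changes results.
#' @param weather Optional weather data.frame (`day`, `vpd_kpa`) used to
#'   scale daily transpiration demand by `vpd / mean(vpd)`; `NULL` keeps
#'   demand constant.
#' @return A list of class `drydown_design`.
#' @export
drydown_design <- function(n_days = 19, n_reps = 2, n_bare = 10,
                           pot_capacity_g = 5000, transpirable_g = 800,
                           evap_g_day = 10, noise_sd_g = 0, seed = 1,
                           weather = NULL) {
  if (transpirable_g >= pot_capacity_g) {
    stop("`transpirable_g` must be smaller than `pot_capacity_g`", call. = FALSE)
  }
  if (any(c(pot_capacity_g, transpirable_g, evap_g_day, noise_sd_g) < 0)) {
    stop("water quantities and noise s.d. must be non-negative", call. = FALSE)
  }
  stopifnot(n_days >= 2, n_reps >= 1, n_bare >= 0)
  demand_mult <- rep(1, n_days)
  if (!is.null(weather)) {
    if (!all(c("day", "vpd_kpa") %in% names(weather))) {
      stop("`weather` needs columns `day` and `vpd_kpa`", call. = FALSE)
    }
    v <- weather$vpd_kpa[match(seq_len(n_days), weather$day)]
    if (anyNA(v)) stop("`weather` must cover days 1..n_days", call. = FALSE)
    demand_mult <- v / mean(v)
  }
  structure(list(n_days = n_days, n_reps = n_reps, n_bare = n_bare,
                 pot_capacity_g = pot_capacity_g,
                 transpirable_g = transpirable_g, evap_g_day = evap_g_day,
                 noise_sd_g = noise_sd_g, seed = as.integer(seed),
                 demand_mult = demand_mult),
            class = "drydown_design")
}

# deterministic per-pot seed below 2^31
pot_seed <- function(seed, pot_index) {
  (as.numeric(seed) * 48271 + pot_index * 65537) %% 2147483629
}

#' Simulate one pot's daily weighing series
#'
#' Explicit daily (Euler) water balance with transpiration computed from
#' start-of-day FTSW, matching the daily weighing cadence:
#' * drought pot — daily demand is `t_pot_g * response_function(FTSW)`;
#'   transpiration and then surface evaporation draw down the transpirable
#'   pool, each capped by the water remaining, so the pool never goes
#'   negative and a dry pot stops losing weight;
#' * irrigated pot — transpires at the well-watered rate every day and is
#'   refilled to its saturated weight after weighing, so the recorded
#'   (pre-rewatering) weight reflects that day's loss;
#' * bare pot — loses `evap_g_day` only.
#'
#' Weighing noise is observation noise: the underlying balance stays exact
#' and only the reported weights are perturbed.
#'
#' @param profile One-row `cultivar_profiles` entry (ignored for bare pots).
#' @param design A [drydown_design()].
#' @param treatment `"drought"`, `"irrigated"` or `"bare"`.
#' @param stream_seed Seed of this pot's private noise stream.
#' @return A data.frame `day`, `weight_g` with attribute `truth`: a
#'   per-day data.frame `day`, `ftsw_true` (start-of-day), `transp_g`,
#'   `evap_g`, `weight_true_g`.
#' @export
simulate_pot_series <- function(profile, design, treatment, stream_seed = 1) {
  n <- design$n_days
  w <- numeric(n)
  transp <- evap <- numeric(n)  # losses realised on day d (interval d-1 -> d)
  ftsw <- rep(NA_real_, n)
  if (treatment == "bare") {
    w <- design$pot_capacity_g - design$evap_g_day * (seq_len(n) - 1)
    evap[-1] <- design$evap_g_day
  } else if (treatment == "irrigated") {
    loss <- design$evap_g_day +
      profile$t_pot_g * profile$plateau_true * design$demand_mult
    grown <- profile$growth_g_day * (seq_len(n) - 1)
    w <- design$pot_capacity_g + grown - loss
    w[1] <- design$pot_capacity_g
    transp[-1] <- (profile$t_pot_g * profile$plateau_true *
                     design$demand_mult)[-1]
    evap[-1] <- design$evap_g_day
    ftsw[] <- 1
  } else if (treatment == "drought") {
    water <- design$transpirable_g
    w[1] <- design$pot_capacity_g
    ftsw[1] <- 1
    for (d in 2:n) {
      f <- water / design$transpirable_g
      demand <- profile$t_pot_g * design$demand_mult[d] *
        response_function(f, profile$ftswc_true, profile$plateau_true)
      transp[d] <- min(demand, water)
      water <- water - transp[d]
      evap[d] <- min(design$evap_g_day, water)
      water <- water - evap[d]
      w[d] <- w[d - 1] - transp[d] - evap[d] + profile$growth_g_day
      ftsw[d] <- water / design$transpirable_g
    }
    ftsw <- c(1, ftsw[-n])  # report start-of-day FTSW
  } else {
    stop("unknown treatment: ", treatment, call. = FALSE)
  }
  reported <- w
  if (design$noise_sd_g > 0) {
    reported <- w + withr_seed(stream_seed,
                               stats::rnorm(n, sd = design$noise_sd_g))
  }
  out <- data.frame(day = seq_len(n), weight_g = reported)
  attr(out, "truth") <- data.frame(day = seq_len(n), ftsw_true = ftsw,
                                   transp_g = transp, evap_g = evap,
                                   weight_true_g = w)
  out
}

#' Simulate a replicated two-treatment dry-down experiment
#'
#' Assembles drought and rewatered-control pots for every cultivar
#' (replicated `n_reps` times each) plus `n_bare` bare evaporation pots
#' into one long-format weighing dataset. Deterministic for a fixed design
#' seed; each pot draws noise from its own stream.
#'
#' @param profiles A [cultivar_profiles()] table (>= 1 row).
#' @param design A [drydown_design()].
#' @param experiment_id Identifier stamped on every row (default `"E1"`).
#' @return A data.frame with columns `experiment_id, pot_id, cultivar,
#'   treatment, replicate, day, weight_g` and attributes `truth` (one row
#'   per cultivar: `cultivar, ftswc_true, plateau_true, t_pot_g`) and
#'   `pot_truth` (per-pot per-day ground-truth list).
#' @export
simulate_experiment <- function(profiles, design, experiment_id = "E1") {
  if (!inherits(profiles, "cultivar_profiles") || nrow(profiles) == 0) {
    stop("`profiles` must be a non-empty cultivar_profiles table", call. = FALSE)
  }
  pots <- list()
  idx <- 0L
  add_pot <- function(profile, treatment, cultivar, replicate) {
    idx <<- idx + 1L
    series <- simulate_pot_series(profile, design, treatment,
                                  stream_seed = pot_seed(design$seed, idx))
    id <- sprintf("P%03d", idx)
    pots[[idx]] <<- list(
      rows = data.frame(experiment_id = experiment_id, pot_id = id,
                        cultivar = cultivar, treatment = treatment,
                        replicate = replicate, day = series$day,
                        weight_g = series$weight_g,
                        stringsAsFactors = FALSE),
      truth = attr(series, "truth"), pot_id = id)
  }
  for (i in seq_len(nrow(profiles))) {
    for (trt in c("drought", "irrigated")) {
      for (r in seq_len(design$n_reps)) {
        add_pot(profiles[i, ], trt, profiles$name[i], r)
      }
    }
  }
  for (b in seq_len(design$n_bare)) add_pot(NULL, "bare", "none", b)
  out <- do.call(rbind, lapply(pots, `[[`, "rows"))
  rownames(out) <- NULL
  truth <- profiles[, c("name", "ftswc_true", "plateau_true", "t_pot_g")]
  names(truth)[1] <- "cultivar"
  attr(out, "truth") <- truth
  pt <- lapply(pots, `[[`, "truth")
  names(pt) <- vapply(pots, `[[`, "", "pot_id")
  attr(out, "pot_truth") <- pt
  out
}

#' Write the simulator's ground truth to a sidecar CSV
#'
#' @param dataset A dataset from [simulate_experiment()].
#' @param path Output path (conventionally `truth.csv`).
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(dataset, path) {
  truth <- attr(dataset, "truth")
  if (is.null(truth)) stop("dataset carries no ground truth", call. = FALSE)
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
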