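#' Validate a long-format weighing dataset
#'
#' Schema: `experiment_id, pot_id, cultivar, treatment, replicate, day,
#' weight_g` with treatment in `{drought, irrigated, bare}`, 1-based integer
#' days without gaps within each pot, positive weights, and one row per
#' pot x day.
#'
#' @param dataset A data.frame in the weighing schema.
#' @return The dataset, ordered by pot and day, invisibly usable downstream.
#' @export
validate_weighing <- function(dataset) {
  need <- c("experiment_id", "pot_id", "cultivar", "treatment",
            "replicate", "day", "weight_g")
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols)) {
    stop("weighing data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_trt <- setdiff(unique(dataset$treatment),
                     c("drought", "irrigated", "bare"))
  if (length(bad_trt)) {
    stop("unknown treatment value(s): ", paste(bad_trt, collapse = ", "),
         call. = FALSE)
  }
  if (any(dataset$weight_g <= 0)) {
    stop("all weights must be positive", call. = FALSE)
  }
  key <- interaction(dataset$experiment_id, dataset$pot_id, drop = TRUE)
  ord <- order(key, dataset$day)
  dataset <- dataset[ord, , drop = FALSE]
  for (pot in split(dataset$day, key[ord])) {
    if (anyDuplicated(pot) || !identical(as.integer(pot),
                                         seq(min(pot), max(pot)))) {
      stop("each pot must have consecutive, unduplicated days", call. = FALSE)
    }
  }
  rownames(dataset) <- NULL
  dataset
}

#' Daily water loss of one pot
#'
#' For a dry-down pot the loss on day `d` is `weight[d-1] - weight[d]`.
#' Irrigated control pots are refilled to their saturated (day-1) weight
#' after each weighing, so the recorded weight is the pre-rewatering weight
#' and the day's loss is `weight[1] - weight[d]`.
#'
#' @param series data.frame with columns `day` and `weight_g` for one pot.
#' @param rewatered Logical; `TRUE` for daily-rewatered (irrigated) pots.
#' @return data.frame `day` (2..n), `loss_g`.
#' @export
daily_water_loss <- function(series, rewatered = FALSE) {
  if (nrow(series) < 2) {
    stop("need at least two weighing days to compute a loss", call. = FALSE)
  }
  d <- series$day
  if (is.unsorted(d, strictly = TRUE)) {
    stop("days must be strictly increasing without duplicates", call. = FALSE)
  }
  w <- series$weight_g
  loss <- if (rewatered) w[1] - w[-1] else -diff(w)
  data.frame(day = d[-1], loss_g = loss)
}

#' Subtract bare-pot evaporation from daily losses
#'
#' Bare pots measure soil surface evaporation; subtracting their mean daily
#' loss from every planted pot's loss leaves the transpiration component.
#' Corrected losses are floored at zero. The correction is applied to
#' drought and irrigated pots symmetrically so the transpiration ratio
#' stays unbiased.
#'
#' @param loss data.frame from [daily_water_loss()].
#' @param bare_mean_loss_g Mean bare-pot loss per day: either a scalar or a
#'   vector aligned with `loss$day`.
#' @return `loss` with an added `loss_corrected_g` column.
#' @export
correct_evaporation <- function(loss, bare_mean_loss_g) {
  if (any(bare_mean_loss_g < 0)) {
    stop("`bare_mean_loss_g` must be non-negative", call. = FALSE)
  }
  if (!length(bare_mean_loss_g) %in% c(1L, nrow(loss))) {
    stop("bare-pot series length does not match the loss series", call. = FALSE)
  }
  loss$loss_corrected_g <- pmax(0, loss$loss_g - bare_mean_loss_g)
  loss
}

#' Transpiration ratio of a drought pot against its controls
#'
#' TR on day `d` is the drought pot's evaporation-corrected loss divided by
#' the mean corrected loss of the paired well-watered control pots on that
#' day; the normalization cancels day-to-day fluctuations in evaporative
#' demand. Days on which the controls lost no water leave TR undefined
#' (`NA`) and are excluded downstream.
#'
#' @param drought Corrected loss data.frame for the drought pot
#'   (from [correct_evaporation()]).
#' @param controls List of corrected loss data.frames for the control pots,
#'   covering the same days.
#' @return data.frame `day`, `tr` (`NA` where undefined).
#' @export
transpiration_ratio <- function(drought, controls) {
  if (!length(controls)) stop("need at least one control series", call. = FALSE)
  ctrl <- vapply(controls, function(cc) {
    if (!identical(cc$day, drought$day)) {
      stop("control series must cover the same days as the drought pot",
           call. = FALSE)
    }
    cc$loss_corrected_g
  }, numeric(nrow(drought)))
  ctrl_mean <- rowMeans(as.matrix(ctrl))
  tr <- ifelse(ctrl_mean > 0, drought$loss_corrected_g / ctrl_mean, NA_real_)
  data.frame(day = drought$day, tr = tr)
}

#' Normalize TR against its well-watered baseline
#'
#' Early in the dry-down the drought pots are still effectively
#' well-watered; the mean TR of days 3 and 5 is taken as that pot's
#' baseline so the normalized transpiration rate (NTR) is ~1 under ample
#' water and declines as the soil dries.
#'
#' @param tr data.frame `day`, `tr` from [transpiration_ratio()].
#' @param baseline_days Days averaged for the baseline (default `c(3, 5)`).
#' @param label Pot label used in error messages.
#' @return data.frame `day`, `tr`, `ntr` with attribute `baseline_tr`.
#' @export
normalize_ntr <- function(tr, baseline_days = c(3, 5), label = "pot") {
  idx <- match(baseline_days, tr$day)
  if (anyNA(idx) || anyNA(tr$tr[idx])) {
    stop(sprintf("%s: baseline day(s) %s missing or undefined", label,
                 paste(baseline_days, collapse = ",")), call. = FALSE)
  }
  baseline <- mean(tr$tr[idx])
  if (baseline <= 0) {
    stop(sprintf("%s: baseline TR is not positive", label), call. = FALSE)
  }
  out <- tr
  out$ntr <- tr$tr / baseline
  attr(out, "baseline_tr") <- baseline
  out
}

#' Fraction of transpirable soil water from raw weights
#'
#' FTSW on day `d` is `(weight[d] - final weight) / (initial - final
#' weight)`, where initial and final are the first and last weighing of the
#' trial: exactly 1 at container capacity and exactly 0 when the
#' transpirable water is exhausted. Values are computed on raw, uncorrected
#' weights and clamped to `[0, 1]` against weighing noise.
#'
#' @param series data.frame `day`, `weight_g` for one pot.
#' @return data.frame `day`, `ftsw`.
#' @export
fraction_tsw <- function(series) {
  w <- series$weight_g
  n <- length(w)
  if (n < 2 || w[1] <= w[n]) {
    stop("degenerate pot: initial weight must exceed final weight",
         call. = FALSE)
  }
  ftsw <- pmin(1, pmax(0, (w - w[n]) / (w[1] - w[n])))
  data.frame(day = series$day, ftsw = ftsw)
}

#' Assemble per-cultivar (FTSW, NTR) response points
#'
#' Runs the full water-balance pipeline over a weighing dataset: daily
#' losses, bare-pot evaporation correction, TR against the mean of all
#' same-cultivar control replicates in the same experiment, NTR against the
#' days-3-and-5 baseline, and FTSW from raw weights. Each drought pot
#' contributes one point per day from day 2 on; the day's NTR (the loss
#' over the interval `d-1 -> d`) is paired with the FTSW at the start of
#' that interval, the soil state that drove the transpiration.
#'
#' Days with undefined NTR are kept in the output but flagged `excluded`
#' with a reason; cultivars that cannot be processed at all (no drought or
#' no control pots, zero control losses on baseline days) are skipped and
#' reported in the `skipped` attribute.
#'
#' @param dataset A weighing data.frame (validated internally).
#' @param baseline_days Baseline days for NTR (default `c(3, 5)`).
#' @param tr_mode `"loss"` (default) computes TR as the ratio of corrected
#'   daily water losses; `"weight_ratio"` applies the literal ratio of raw
#'   pot weights instead.
#' @param ftsw_day `"start"` (default) pairs a day's NTR with the FTSW at
#'   the start of the loss interval; `"end"` uses the same day's FTSW.
#' @return data.frame `cultivar, replicate, day, ftsw, ntr, excluded,
#'   reason`, with attribute `skipped` (data.frame `cultivar, reason`).
#' @export
build_response_points <- function(dataset, baseline_days = c(3, 5),
                                  tr_mode = c("loss", "weight_ratio"),
                                  ftsw_day = c("start", "end")) {
  tr_mode <- match.arg(tr_mode)
  ftsw_day <- match.arg(ftsw_day)
  dataset <- validate_weighing(dataset)
  out <- list()
  skipped <- list()
  for (exp_id in unique(dataset$experiment_id)) {
    ds <- dataset[dataset$experiment_id == exp_id, ]
    bare <- ds[ds$treatment == "bare", ]
    bare_loss <- 0
    if (nrow(bare)) {
      per_pot <- lapply(split(bare, bare$pot_id), daily_water_loss)
      bare_loss <- rowMeans(vapply(per_pot, `[[`, numeric(nrow(per_pot[[1]])),
                                   "loss_g"))
    }
    for (cv in setdiff(unique(ds$cultivar), "none")) {
      dcv <- ds[ds$cultivar == cv, ]
      droughts <- split(dcv[dcv$treatment == "drought", ],
                        dcv$pot_id[dcv$treatment == "drought"], drop = TRUE)
      ctrls <- split(dcv[dcv$treatment == "irrigated", ],
                     dcv$pot_id[dcv$treatment == "irrigated"], drop = TRUE)
      if (!length(droughts) || !length(ctrls)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          cultivar = cv, experiment_id = exp_id,
          reason = "missing drought or control pots")
        next
      }
      ctrl_corr <- lapply(ctrls, function(p) {
        correct_evaporation(daily_water_loss(p, rewatered = TRUE), bare_loss)
      })
      for (pot in droughts) {
        pot_label <- sprintf("%s/%s", exp_id, pot$pot_id[1])
        tr <- if (tr_mode == "loss") {
          dl <- correct_evaporation(daily_water_loss(pot), bare_loss)
          transpiration_ratio(dl, ctrl_corr)
        } else {
          cw <- rowMeans(vapply(ctrls, `[[`, numeric(nrow(pot)), "weight_g"))
          data.frame(day = pot$day[-1],
                     tr = (pot$weight_g / cw)[-1])
        }
        ntr <- tryCatch(normalize_ntr(tr, baseline_days, label = pot_label),
                        error = function(e) e)
        if (inherits(ntr, "error")) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            cultivar = cv, experiment_id = exp_id,
            reason = conditionMessage(ntr))
          next
        }
        ftsw <- fraction_tsw(pot)
        f_by_day <- ftsw$ftsw[match(
          if (ftsw_day == "start") ntr$day - 1L else ntr$day, ftsw$day)]
        pts <- data.frame(cultivar = cv, replicate = pot$replicate[1],
                          day = ntr$day, ftsw = f_by_day, ntr = ntr$ntr,
                          stringsAsFactors = FALSE)
        pts$excluded <- !is.finite(pts$ntr) | !is.finite(pts$ftsw)
        pts$reason <- ifelse(pts$excluded, "undefined NTR or FTSW", "")
        out[[length(out) + 1L]] <- pts
      }
    }
  }
  points <- if (length(out)) do.call(rbind, out) else
    data.frame(cultivar = character(), replicate = integer(),
               day = integer(), ftsw = numeric(), ntr = numeric(),
               excluded = logical(), reason = character())
  rownames(points) <- NULL
  attr(points, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(cultivar = character(), experiment_id = character(),
               reason = character())
  }
  points
}
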