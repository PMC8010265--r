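#' Load the packaged 80-cultivar reference table
#'
#' The package ships a transcription of the reference panel of 80 white
#' clover cultivars released 1920-2010: release decade, country of origin,
#' registered leaf size, total plant dry weights under the drought and
#' irrigated treatments (g), and the critical FTSW threshold where one was
#' obtained. A "/" in the source — a cultivar whose dry-down yielded no
#' threshold — is encoded as `NA` and excluded from all FTSWc statistics
#' (59 defined values), never imputed.
#'
#' Loading validates the transcription: 80 records, positive dry weights,
#' leaf-size tallies as printed in the table itself (1 small, 52 medium,
#' 27 large; the source's prose summary says 53/26, a discrepancy the
#' table resolves), and an md5 digest of the packaged file.
#'
#' @return data.frame of class `table1_fixture`: `cultivar`, `decade`,
#'   `country`, `leaf_size`, `dw_drought_g`, `dw_irrigated_g`, `ftswc`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cultivars.csv", package = "drydownr",
                      mustWork = TRUE)
  digest <- unname(tools::md5sum(path))
  if (!identical(digest, "802ca7946060943d769261bac72ee056")) {
    stop("packaged cultivar table failed its integrity check (md5 ",
         digest, ")", call. = FALSE)
  }
  t1 <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "integer", "character",
                                       "character", "numeric", "numeric",
                                       "numeric"))
  stopifnot(nrow(t1) == 80,
            identical(names(t1), c("cultivar", "decade", "country",
                                   "leaf_size", "dw_drought_g",
                                   "dw_irrigated_g", "ftswc")),
            all(t1$dw_drought_g > 0), all(t1$dw_irrigated_g > 0),
            sum(t1$leaf_size == "small") == 1,
            sum(t1$leaf_size == "medium") == 52,
            sum(t1$leaf_size == "large") == 27,
            sum(!is.na(t1$ftswc)) == 59)
  class(t1) <- c("table1_fixture", "data.frame")
  t1
}

#' Summarize the critical FTSW thresholds of the reference panel
#'
#' Mean, minimum and maximum over the defined thresholds only, with the
#' extreme cultivars named. Note the source's prose quotes a range of
#' 0.11-0.50 while its own table's extremes are 0.12 (AberHerald) and 0.52
#' (Tribute); the statistics here are computed from the table.
#'
#' @param fixture A [load_table1_fixture()] table (or any data.frame with
#'   `cultivar` and `ftswc`).
#' @return list: `n_defined`, `mean`, `min`, `max`, `argmin`, `argmax`
#'   (full precision; round for presentation).
#' @export
summarize_ftswc <- function(fixture = load_table1_fixture()) {
  v <- fixture$ftswc
  if (!any(is.finite(v))) stop("no defined FTSWc values", call. = FALSE)
  ok <- which(is.finite(v))
  list(n_defined = length(ok), mean = mean(v[ok]),
       min = min(v[ok]), max = max(v[ok]),
       argmin = fixture$cultivar[ok[which.min(v[ok])]],
       argmax = fixture$cultivar[ok[which.max(v[ok])]])
}

#' Rank cultivars by their critical FTSW threshold
#'
#' A low threshold marks a cultivar that keeps transpiring in drier soil
#' (suited to short droughts); a high threshold marks early stomatal
#' closure and water banking (suited to long droughts). Ties are broken
#' alphabetically and flagged.
#'
#' @param fixture Table with `cultivar` and `ftswc`.
#' @param k How many cultivars at each extreme.
#' @return list with data.frames `bottom` (ascending) and `top`
#'   (descending), each `cultivar`, `ftswc`, `tied`.
#' @export
rank_cultivars <- function(fixture = load_table1_fixture(), k = 5) {
  ok <- fixture[is.finite(fixture$ftswc), c("cultivar", "ftswc")]
  if (k < 1 || k > nrow(ok)) {
    stop("`k` must be between 1 and the number of defined values (",
         nrow(ok), ")", call. = FALSE)
  }
  take <- function(decreasing) {
    o <- order(ok$ftswc, ok$cultivar, decreasing = c(decreasing, FALSE),
               method = "radix")
    sel <- ok[o[seq_len(k)], ]
    sel$tied <- vapply(sel$ftswc, function(x) sum(ok$ftswc == x) > 1,
                       logical(1))
    rownames(sel) <- NULL
    sel
  }
  list(bottom = take(FALSE), top = take(TRUE))
}

#' Summarize the dry weights of the reference panel
#'
#' Means and ranges of total plant dry weight (g) under the drought and
#' irrigated treatments, over all 80 cultivars, with the extreme cultivars
#' named.
#'
#' @param fixture A [load_table1_fixture()] table.
#' @return list with components `drought` and `irrigated`, each holding
#'   `mean`, `min`, `max`, `argmin`, `argmax`.
#' @export
summarize_dry_weights <- function(fixture = load_table1_fixture()) {
  one <- function(v) list(mean = mean(v), min = min(v), max = max(v),
                          argmin = fixture$cultivar[which.min(v)],
                          argmax = fixture$cultivar[which.max(v)])
  list(drought = one(fixture$dw_drought_g),
       irrigated = one(fixture$dw_irrigated_g))
}

#' Round half to even at a fixed number of decimals
#'
#' Presentation rounding used in reports; internal values always keep full
#' precision. (Base R's `round()` already rounds half to even; this wrapper
#' just names the convention.)
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round2 <- function(x, digits = 2) round(x, digits)

#' Read / write the long-format weighing CSV
#'
#' Schema: `experiment_id,pot_id,cultivar,treatment,replicate,day,weight_g`
#' with `treatment` in `{drought, irrigated, bare}` and 1-based integer
#' days. Reading validates the schema; writing preserves column order so a
#' write-then-read round trip is value-identical.
#'
#' @param path CSV path.
#' @return `read_weighing_csv()`: a validated weighing data.frame.
#' @export
read_weighing_csv <- function(path) {
  validate_weighing(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_weighing_csv
#' @param dataset A weighing data.frame.
#' @return `write_weighing_csv()`: `path`, invisibly.
#' @export
write_weighing_csv <- function(dataset, path) {
  cols <- c("experiment_id", "pot_id", "cultivar", "treatment", "replicate",
            "day", "weight_g")
  utils::write.csv(dataset[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-cultivar response-point CSV
#'
#' Columns: `cultivar,replicate,day,ftsw,ntr,excluded,reason`.
#'
#' @param points Table from [build_response_points()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_points_csv <- function(points, path) {
  cols <- c("cultivar", "replicate", "day", "ftsw", "ntr", "excluded",
            "reason")
  utils::write.csv(points[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write the per-cultivar fit results CSV
#'
#' Columns: `cultivar,n_points,A,A_lo,A_hi,B,B_lo,B_hi,ftswc,ftswc_lo,
#' ftswc_hi,plateau,slope,sse,converged`.
#'
#' @param results Table from [fit_all_cultivars()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  cols <- c("cultivar", "n_points", "A", "A_lo", "A_hi", "B", "B_lo",
            "B_hi", "ftswc", "ftswc_lo", "ftswc_hi", "plateau", "slope",
            "sse", "converged")
  utils::write.csv(results[cols], path, row.names = FALSE)
  invisible(path)
}
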