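#' Saturation vapor pressure of air
#'
#' Tetens-type exponential approximation used throughout glasshouse
#' micrometeorology: `es = 0.6108 * exp(17.27 * Ta / (Ta + 237.3))`, with
#' air temperature `Ta` in degrees Celsius and the result in kilopascals.
#' The 0.6108 constant fixes the unit as kPa; no implicit conversions are
#' performed anywhere in the package.
#'
#' @param temp_c Air temperature in degrees C. Vectorized. Must exceed
#'   -237.3 (the denominator `Ta + 237.3` must stay positive).
#' @return Saturation vapor pressure in kPa, same length as `temp_c`.
#'   Strictly increasing in temperature.
#' @examples
#' saturation_vapor_pressure(0)     # 0.6108 kPa
#' saturation_vapor_pressure(22.39) # ~2.707 kPa
#' @export
saturation_vapor_pressure <- function(temp_c) {
  if (!is.numeric(temp_c) || anyNA(temp_c)) {
    stop("`temp_c` must be numeric with no missing values", call. = FALSE)
  }
  if (any(temp_c <= -237.3)) {
    stop("`temp_c` must be > -237.3 degC", call. = FALSE)
  }
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Vapor pressure deficit
#'
#' VPD is the difference between the saturation vapor pressure at air
#' temperature and the actual vapor pressure, `ea = (RH/100) * es`. It is
#' the atmospheric demand that drives transpiration; saturated air
#' (RH = 100%) has a VPD of exactly zero.
#'
#' Relative humidity is accepted in percent, never as a fraction. If every
#' supplied value is <= 1 the input looks like a fraction and a warning is
#' issued, but no auto-conversion is performed: silent unit guessing
#' corrupts results.
#'
#' @param temp_c Air temperature in degrees C (vectorized).
#' @param rh_pct Relative humidity in percent, in `[0, 100]` (vectorized,
#'   recycled against `temp_c` by the usual rules).
#' @return A data.frame with columns `es_kpa`, `ea_kpa` and `vpd_kpa`
#'   (all in kPa), one row per element.
#' @examples
#' vpd(25, 100)          # saturated air, vpd = 0
#' vpd(22.39, 57.00)     # ~1.164 kPa
#' @export
vpd <- function(temp_c, rh_pct) {
  if (!is.numeric(rh_pct) || anyNA(rh_pct)) {
    stop("`rh_pct` must be numeric with no missing values", call. = FALSE)
  }
  if (any(rh_pct < 0 | rh_pct > 100)) {
    stop("`rh_pct` must lie in [0, 100] percent", call. = FALSE)
  }
  if (length(rh_pct) > 0 && all(rh_pct <= 1)) {
    warning("all `rh_pct` values are <= 1; relative humidity is expected ",
            "in percent, not as a fraction (values left unchanged)",
            call. = FALSE)
  }
  es <- saturation_vapor_pressure(temp_c)
  ea <- (rh_pct / 100) * es
  data.frame(es_kpa = es, ea_kpa = ea, vpd_kpa = es - ea)
}

#' Read a daily weather table
#'
#' Expects a headed CSV with columns `day,temp_c,rh_pct,solar_mj_m2`
#' ('.' decimal separator). Solar radiation (MJ/m2/day) is carried along
#' for reporting but takes no part in any computation.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame with the four columns above plus the
#'   derived `es_kpa`, `ea_kpa`, `vpd_kpa`.
#' @export
read_weather_csv <- function(path) {
  wx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "temp_c", "rh_pct", "solar_mj_m2")
  missing_cols <- setdiff(need, names(wx))
  if (length(missing_cols)) {
    stop("weather CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  wx <- wx[need]
  v <- vpd(wx$temp_c, wx$rh_pct)
  cbind(wx, v)
}
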