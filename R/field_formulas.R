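#' Growing-degree-day schedule for managed drought stress
#'
#' Named thermal-time checkpoints used to impose reproductive-stage drought in
#' managed trials: irrigation is withdrawn once 550 cumulative growing degree
#' days (GDD, base 10 degrees C) have accumulated from the last life
#' irrigation, and the stress is relieved by a rescue irrigation at 1000
#' cumulative GDD.
#'
#' @format Named numeric vector with elements `withdrawal` (550) and
#'   `rescue` (1000), in degree-day units.
#' @export
gdd_stress_schedule <- c(withdrawal = 550, rescue = 1000)

#' Cumulative growing degree days
#'
#' Thermal time accumulated over a daily weather series,
#' \eqn{\sum \max((T_{max}+T_{min})/2 - T_{base}, 0)}.  Days whose mean
#' temperature falls below the base temperature contribute zero (the daily
#' increment is floored at zero, the standard agronomic convention), so the
#' running sum is non-negative and non-decreasing.
#'
#' @param tmax,tmin daily maximum and minimum temperatures (degrees C), in
#'   chronological order; `tmax >= tmin` element-wise.
#' @param tbase base temperature, default 10 degrees C (maize).
#' @return Numeric vector of cumulative GDD, one element per day.
#' @examples
#' cumulative_gdd(c(30, 28), c(20, 22))  # 15, 30
#' @export
cumulative_gdd <- function(tmax, tmin, tbase = 10) {
  tmax <- as.numeric(tmax); tmin <- as.numeric(tmin)
  if (length(tmax) != length(tmin))
    stop("tmax and tmin must have the same length", call. = FALSE)
  if (any(tmax < tmin, na.rm = TRUE))
    stop("tmax < tmin in weather records", call. = FALSE)
  cumsum(pmax((tmax + tmin) / 2 - tbase, 0))
}

#' Standardize plot harvest weight to grain yield at fixed moisture
#'
#' Converts fresh ear weight per plot to grain yield in t/ha at a standardized
#' moisture content:
#' \deqn{GY = \frac{FW \times 10 \times (100 - MC) \times SH}
#'                 {(100 - MC_{adj}) \times A}}
#' where \eqn{FW} is fresh ear weight (kg/plot), \eqn{MC} the measured grain
#' moisture (%), \eqn{SH} the shelling fraction in \[0, 1\], \eqn{A} the plot
#' area (m^2) and \eqn{MC_{adj}} the standardized moisture (12.5% by default).
#' The result is linear in both `fresh_ear_weight` and `shelling`.
#'
#' @param fresh_ear_weight fresh ear weight without husk, kg/plot.
#' @param moisture measured grain moisture content, percent, in \[0, 100).
#' @param shelling shelling fraction (grain weight / ear weight), in \[0, 1\].
#' @param plot_area harvested plot area, m^2 (> 0).
#' @param adjusted_moisture standardized moisture percentage, default 12.5.
#' @return Grain yield in t/ha.
#' @examples
#' standardize_grain_yield(6, 12.5, 1, 6)    # 10 t/ha
#' standardize_grain_yield(6, 12.5, 0.8, 6)  # 8 t/ha
#' @export
standardize_grain_yield <- function(fresh_ear_weight, moisture, shelling,
                                    plot_area, adjusted_moisture = 12.5) {
  if (any(moisture < 0 | moisture >= 100))
    stop("moisture must be in [0, 100)", call. = FALSE)
  if (any(plot_area <= 0)) stop("plot_area must be > 0", call. = FALSE)
  if (any(shelling < 0 | shelling > 1))
    stop("shelling must be a fraction in [0, 1]", call. = FALSE)
  if (any(adjusted_moisture < 0 | adjusted_moisture >= 100))
    stop("adjusted_moisture must be in [0, 100)", call. = FALSE)
  fresh_ear_weight * 10 * (100 - moisture) * shelling /
    ((100 - adjusted_moisture) * plot_area)
}
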