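#' Heat-pulse protocol
#'
#' Describes one optically applied heat pulse: a focused IR laser is switched
#' on at `t_start` seconds after the start of observation and shut off
#' `duration` seconds later, at ambient (stage incubator) base temperature
#' `T0`.
#'
#' @param t_start Pulse onset, seconds from the start of observation.
#' @param duration Pulse duration in seconds.
#' @param laser_power Laser power at the sample, mW.
#' @param T0 Base temperature in degrees Celsius. Calibration slopes for the
#'   temperature dye exist at 24 and 36 degrees C; other values are allowed
#'   here but conversion to temperature requires a matching slope.
#' @param observation_start Time origin of the recording, seconds (normally 0).
#' @return An object of class `heat_protocol`.
#' @examples
#' heat_protocol(laser_power = 25.6, T0 = 24)
#' @export
heat_protocol <- function(t_start = 10, duration = 2, laser_power = 25.6,
                          T0 = 24, observation_start = 0) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L, t_start >= 0,
            is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(laser_power), length(laser_power) == 1L, laser_power >= 0,
            is.numeric(T0), length(T0) == 1L, is.finite(T0))
  structure(list(t_start = t_start, duration = duration,
                 laser_power = laser_power, T0 = T0,
                 observation_start = observation_start),
            class = "heat_protocol")
}

#' @export
print.heat_protocol <- function(x, ...) {
  cat(sprintf("Heat pulse: %g s at t = %g s, %g mW, T0 = %g degC\n",
              x$duration, x$t_start, x$laser_power, x$T0))
  invisible(x)
}

#' Thermal-quenching calibration curve for the temperature dye
#'
#' Fractional intensity change of Eu-TTA luminescence per degree of heating,
#' as a function of base temperature. The published slopes are -2.7% per
#' degree C at 24 degrees C and -4.1% per degree C at 36 degrees C; lookups at
#' any other base temperature fail loudly rather than extrapolate. Supply
#' `slopes` to add user-measured values (e.g. mapping a 23 degree muscle
#' experiment onto the 24 degree slope, at your own risk).
#'
#' @param slopes Named numeric vector, names are base temperatures in degrees
#'   C, values are fractional intensity changes per degree C (all negative).
#' @return An object of class `calibration_curve`.
#' @examples
#' cal <- calibration_curve()
#' cal_slope(cal, 24)  # -0.027
#' @export
calibration_curve <- function(slopes = c("24" = -0.027, "36" = -0.041)) {
  stopifnot(is.numeric(slopes), length(slopes) >= 1L, !is.null(names(slopes)))
  if (any(slopes >= 0)) stop("all quenching slopes must be negative")
  structure(list(slopes = slopes), class = "calibration_curve")
}

#' @rdname calibration_curve
#' @param cal A `calibration_curve`.
#' @param T0 Base temperature in degrees C.
#' @export
cal_slope <- function(cal, T0) {
  stopifnot(inherits(cal, "calibration_curve"))
  key <- as.character(T0)
  if (!key %in% names(cal$slopes)) {
    stop(sprintf("no calibration slope for T0 = %s degC (supported: %s)",
                 key, paste(names(cal$slopes), collapse = ", ")))
  }
  unname(cal$slopes[key])
}

#' Background intensity estimates
#'
#' `i_back` is the background intensity with the excitation light off (camera
#' dark level plus stray light). `i_laser` is the total background during
#' laser-on frames, i.e. what a cell-free region reads while the IR beam is
#' on: the dark level plus IR-scatter. Both in the arbitrary units of the
#' recording.
#'
#' @param i_back Excitation-off background, a.u. (>= 0).
#' @param i_laser Laser-on background, a.u. (>= 0).
#' @return An object of class `background_estimates`.
#' @export
background_estimates <- function(i_back = 0, i_laser = 0) {
  stopifnot(is.numeric(i_back), length(i_back) == 1L, i_back >= 0,
            is.numeric(i_laser), length(i_laser) == 1L, i_laser >= 0)
  structure(list(i_back = i_back, i_laser = i_laser),
            class = "background_estimates")
}

#' Single-ROI fluorescence time series
#'
#' One cell's (or one region's) intensity trace, with the indicator channel,
#' the distance from the ROI centre to the heat source, and per-frame laser-on
#' flags.
#'
#' @param time_s Frame times in seconds, strictly increasing.
#' @param intensity_au Intensities, arbitrary units, finite.
#' @param laser_on Logical (or 0/1) per frame; defaults to all off.
#' @param cell_id Identifier string.
#' @param channel One of "fluo4", "cal520", "cepia", "eutta".
#' @param distance_um Distance to the heat source in micrometres (NA allowed
#'   for unheated reference cells).
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(time_s, intensity_au, laser_on = NULL,
                        cell_id = "cell", channel = "fluo4",
                        distance_um = NA_real_) {
  stopifnot(is.numeric(time_s), is.numeric(intensity_au),
            length(time_s) == length(intensity_au), length(time_s) >= 1L)
  if (any(!is.finite(intensity_au))) stop("non-finite intensities in trace")
  if (any(diff(time_s) <= 0)) stop("trace times must be strictly increasing")
  if (is.null(laser_on)) laser_on <- rep(FALSE, length(time_s))
  laser_on <- as.logical(laser_on)
  stopifnot(length(laser_on) == length(time_s))
  channel <- match.arg(channel, c("fluo4", "cal520", "cepia", "eutta"))
  structure(list(time_s = as.numeric(time_s),
                 intensity_au = as.numeric(intensity_au),
                 laser_on = laser_on,
                 cell_id = as.character(cell_id),
                 channel = channel,
                 distance_um = as.numeric(distance_um)),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace %s [%s] %d frames, %g-%g s, r = %s um>\n",
              x$cell_id, x$channel, length(x$time_s),
              min(x$time_s), max(x$time_s),
              format(x$distance_um)))
  invisible(x)
}

# frame index of the last frame at or before time t (half-frame tolerance)
frame_at_or_before <- function(trace, t) {
  idx <- which(trace$time_s <= t + 1e-9)
  if (length(idx) == 0L) {
    stop(sprintf("trace '%s' has no frame at or before t = %g s",
                 trace$cell_id, t))
  }
  max(idx)
}

# logical index of laser-on frames, from flags if set, else from the protocol
laser_on_frames <- function(trace, protocol) {
  if (any(trace$laser_on)) return(trace$laser_on)
  t0 <- protocol$t_start
  trace$time_s > t0 + 1e-9 & trace$time_s <= t0 + protocol$duration + 1e-9
}
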