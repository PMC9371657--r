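#' Correct photobleaching by a single-exponential fit
#'
#' Fits `I(t) = A exp(-k t)` to the trace inside `fit_window` (by default the
#' pre-stimulus segment, which is uncontaminated by heating) and divides the
#' whole trace by `exp(-k t)` (unit value at t = 0). If the fitted rate is
#' not positive the trace is returned unchanged and flagged.
#'
#' @param trace A [fluor_trace()].
#' @param fit_window Length-2 numeric, seconds; frames with
#'   `fit_window[1] <= t <= fit_window[2]` are used for the fit (>= 5 frames,
#'   all intensities > 0).
#' @return The corrected [fluor_trace()] with attribute `bleach`: list with
#'   the fitted rate `k` (1/s) and `corrected` (logical).
#' @export
correct_photobleaching <- function(trace, fit_window = c(0, 10)) {
  stopifnot(inherits(trace, "fluor_trace"), length(fit_window) == 2L)
  sel <- trace$time_s >= fit_window[1] - 1e-9 & trace$time_s <= fit_window[2] + 1e-9
  if (!any(sel)) stop("fit window lies outside the trace")
  if (sum(sel) < 5L) stop("fit window must contain at least 5 frames")
  tt <- trace$time_s[sel]
  yy <- trace$intensity_au[sel]
  if (any(!is.finite(yy))) stop("non-finite values in fit window")
  if (any(yy <= 0)) stop("non-positive intensities in fit window")
  # log-linear start values, then least squares on the original scale
  lf <- stats::lm(log(yy) ~ tt)
  k0 <- -unname(stats::coef(lf)[2])
  a0 <- exp(unname(stats::coef(lf)[1]))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(yy ~ a * exp(-k * tt), start = list(a = a0, k = k0),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  k <- if (is.null(fit)) k0 else unname(stats::coef(fit)["k"])
  if (!is.finite(k) || k <= 0) {
    attr(trace, "bleach") <- list(k = k, corrected = FALSE)
    return(trace)
  }
  out <- trace
  out$intensity_au <- trace$intensity_au / exp(-k * trace$time_s)
  attr(out, "bleach") <- list(k = k, corrected = TRUE)
  out
}

#' Quench ratio of a temperature-dye trace
#'
#' Computes `dF/F0 = (F_heating - I_laser) / (F_before - I_back) - 1`, where
#' `F_heating` is the dye intensity at the end of the heating period (just
#' before the IR beam is shut off; for robustness the mean of the final two
#' laser-on frames), `F_before` the intensity just before heating was
#' initiated, `I_laser` the laser-on background and `I_back` the
#' excitation-off background.
#'
#' @param trace A (bleach-corrected) [fluor_trace()] of the temperature dye.
#' @param protocol A [heat_protocol()].
#' @param bg A [background_estimates()].
#' @return The dimensionless quench ratio (negative when heated).
#' @export
quench_ratio <- function(trace, protocol, bg) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(protocol, "heat_protocol"),
            inherits(bg, "background_estimates"))
  on <- laser_on_frames(trace, protocol)
  if (!any(on)) stop("trace has no laser-on frames; cannot locate end of heating")
  t_end <- protocol$t_start + protocol$duration
  dt <- if (length(trace$time_s) > 1L) min(diff(trace$time_s)) else 0
  if (max(trace$time_s) < t_end - dt - 1e-9) {
    stop("trace does not cover the end of the heating period")
  }
  idx_on <- which(on)
  idx_last <- utils::tail(idx_on, 2L)
  f_heating <- mean(trace$intensity_au[idx_last])
  f_before <- trace$intensity_au[frame_at_or_before(trace, protocol$t_start)]
  denom <- f_before - bg$i_back
  if (denom <= 0) stop("dead baseline: F_before - I_back must be positive")
  (f_heating - bg$i_laser) / denom - 1
}

#' Convert a quench ratio to a temperature rise
#'
#' `dT = ratio / slope(T0)` with the thermal-quenching slope of the dye at
#' the base temperature (-2.7% per degC at 24 degC, -4.1% per degC at
#' 36 degC). Unknown base temperatures raise an error listing the supported
#' values; there is no extrapolation.
#'
#' @param ratio Quench ratio (dimensionless; negative when heated).
#' @param T0 Base temperature, degC.
#' @param cal A [calibration_curve()].
#' @return Temperature rise in degC (positive for a negative ratio).
#' @examples
#' to_delta_T(-0.027, 24)  # 1 degC
#' @export
to_delta_T <- function(ratio, T0, cal = calibration_curve()) {
  ratio / cal_slope(cal, T0)
}

#' Temperature profile from a dye-sheet measurement
#'
#' Runs the full thermometry chain on a set of temperature-dye traces
#' recorded at known distances from the heat source: photobleaching
#' correction (pre-stimulus window), quench ratio, conversion to a
#' temperature rise, isotonic regularisation (the rise must not increase
#' with distance), and averaging over duplicated distances.
#'
#' @param sheet_traces List of [fluor_trace()] with channel "eutta" and
#'   finite distances; at least 3 distinct distances.
#' @param protocol A [heat_protocol()].
#' @param bg A [background_estimates()].
#' @param cal A [calibration_curve()].
#' @param bleach_window Fit window for photobleaching correction (default the
#'   pre-stimulus segment).
#' @return An object of class `sheet_profile`: data frame with `distance_um`
#'   and `deltaT_C` (one row per distinct distance, isotonic in distance).
#' @seealso [assign_delta_T()] to interpolate per-cell temperature rises.
#' @export
profile_from_sheet <- function(sheet_traces, protocol, bg,
                               cal = calibration_curve(),
                               bleach_window = c(0, protocol$t_start)) {
  stopifnot(length(sheet_traces) >= 1L)
  r <- vapply(sheet_traces, function(tr) tr$distance_um, numeric(1))
  if (any(!is.finite(r)) || any(r <= 0)) stop("all sheet traces need positive distances")
  if (length(unique(r)) < 3L) stop("need at least 3 distinct sheet distances")
  dT <- vapply(sheet_traces, function(tr) {
    trc <- correct_photobleaching(tr, bleach_window)
    to_delta_T(quench_ratio(trc, protocol, bg), protocol$T0, cal)
  }, numeric(1))
  # average duplicates, then enforce monotone decay with distance
  agg <- stats::aggregate(list(deltaT_C = dT), by = list(distance_um = r), FUN = mean)
  agg <- agg[order(agg$distance_um), ]
  iso <- stats::isoreg(agg$distance_um, -agg$deltaT_C)
  agg$deltaT_C <- -iso$yf
  if (all(abs(agg$deltaT_C) < 1e-12)) {
    warning("all sheet temperature rises are zero")
  }
  structure(agg, class = c("sheet_profile", "data.frame"))
}

#' Assign per-cell temperature rises from a sheet profile
#'
#' Interpolates the measured profile at each cell's distance in log-log
#' space (the field decays roughly as an inverse power of distance, so
#' log-temperature is nearly linear in log-distance); if any measured rise
#' is non-positive the interpolation falls back to linear-in-log-distance.
#' Distances outside the measured range take the nearest measured value.
#'
#' @param profile A `sheet_profile` from [profile_from_sheet()].
#' @param distances_um Cell distances, um (> 0).
#' @return Numeric vector of temperature rises, degC.
#' @export
assign_delta_T <- function(profile, distances_um) {
  stopifnot(inherits(profile, "sheet_profile"), all(distances_um > 0))
  if (all(profile$deltaT_C > 0)) {
    exp(stats::approx(log(profile$distance_um), log(profile$deltaT_C),
                      xout = log(distances_um), rule = 2, ties = "ordered")$y)
  } else {
    stats::approx(log(profile$distance_um), profile$deltaT_C,
                  xout = log(distances_um), rule = 2, ties = "ordered")$y
  }
}
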