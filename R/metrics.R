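#' Baseline statistics of a cell trace
#'
#' `f_before` is the intensity of the frame at (or immediately before) the
#' pulse onset -- no smoothing -- and the basal fluorescence is
#' `f0 = f_before - i_back`.
#'
#' @param trace A [fluor_trace()].
#' @param protocol A [heat_protocol()].
#' @param bg A [background_estimates()].
#' @return List of class `baseline_stats` with `f_before` and `f0` (a.u.).
#' @export
baseline <- function(trace, protocol, bg) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(protocol, "heat_protocol"),
            inherits(bg, "background_estimates"))
  f_before <- trace$intensity_au[frame_at_or_before(trace, protocol$t_start)]
  f0 <- f_before - bg$i_back
  if (f0 <= 0) stop(sprintf("cell '%s': F_before <= I_back (dead baseline)",
                            trace$cell_id))
  structure(list(f_before = f_before, f0 = f0), class = "baseline_stats")
}

#' Subtract IR-scatter background from laser-on frames
#'
#' The IR beam adds a scatter background only while it is on. This removes
#' the scatter component (`i_laser - i_back`, i.e. the laser-on background in
#' excess of the dark background) from laser-on frames, leaving all other
#' frames untouched, so that on- and off-pulse frames share the same
#' additive offset.
#'
#' @inheritParams baseline
#' @return The corrected [fluor_trace()].
#' @export
scatter_correct <- function(trace, bg, protocol) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(bg, "background_estimates"))
  scatter <- bg$i_laser - bg$i_back
  if (scatter == 0) return(trace)
  on <- laser_on_frames(trace, protocol)
  trace$intensity_au[on] <- trace$intensity_au[on] - scatter
  trace
}

# checks that the trace covers [t_lo, t_hi] (half-frame tolerance) and
# returns the logical frame selection for the closed window
window_frames <- function(trace, t_lo, t_hi, what = "analysis") {
  dt <- if (length(trace$time_s) > 1L) min(diff(trace$time_s)) else 0
  if (trace$time_s[1] > t_lo + dt / 2 || max(trace$time_s) < t_hi - dt / 2) {
    stop(sprintf("cell '%s': trace does not cover the %s window [%g, %g] s",
                 trace$cell_id, what, t_lo, t_hi))
  }
  trace$time_s >= t_lo - dt / 2 & trace$time_s <= t_hi + dt / 2
}

#' Peak burst statistic dF_max/F0
#'
#' The maximum of `(F - F_before)/F0` during the `window_s` seconds after
#' heating initiation (closed window), on a scatter-corrected trace.
#'
#' @param trace A scatter-corrected [fluor_trace()] (see [scatter_correct()]).
#' @param protocol A [heat_protocol()].
#' @param bg A [background_estimates()].
#' @param window_s Analysis window length after pulse onset, s (default 20).
#' @return List of class `burst_metrics` with `dfmax`, `t_peak_s`, and the
#'   baseline used.
#' @export
dfmax <- function(trace, protocol, bg, window_s = 20) {
  bs <- baseline(trace, protocol, bg)
  sel <- window_frames(trace, protocol$t_start, protocol$t_start + window_s,
                       "burst")
  rel <- (trace$intensity_au[sel] - bs$f_before) / bs$f0
  i <- which.max(rel)
  structure(list(cell_id = trace$cell_id, channel = trace$channel,
                 dfmax = rel[i], t_peak_s = trace$time_s[sel][i],
                 f_before = bs$f_before, f0 = bs$f0),
            class = "burst_metrics")
}

#' Spontaneous-fluctuation statistic for unheated cells
#'
#' `(F_max - F_before)/(F_before - I_back)` where `F_before` is the intensity
#' at `window[1]` seconds after the start of observation (matching the
#' excitation exposure of the heating experiments) and `F_max` the maximum
#' from `window[1]` to `window[2]` seconds (closed window).
#'
#' @param trace A [fluor_trace()] from an unheated cell.
#' @param bg A [background_estimates()].
#' @param window Length-2 numeric, s (default `c(10, 30)`).
#' @return The dimensionless fluctuation statistic.
#' @export
spontaneous_dfmax <- function(trace, bg, window = c(10, 30)) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(bg, "background_estimates"),
            length(window) == 2L)
  f_before <- trace$intensity_au[frame_at_or_before(trace, window[1])]
  f0 <- f_before - bg$i_back
  if (f0 <= 0) stop(sprintf("cell '%s': F_before <= I_back (dead baseline)",
                            trace$cell_id))
  sel <- window_frames(trace, window[1], window[2], "fluctuation")
  (max(trace$intensity_au[sel]) - f_before) / f0
}

#' ER store-depletion statistic dF_min/F0
#'
#' For ER-luminal indicator traces: the minimum of `(F - F_before)/F0` in a
#' window from `window[1]` to `window[2]` seconds after heating initiation
#' (default 2.4 to 10 s, which excludes the thermal-quenching epoch during
#' the pulse). The trace should be bleach-corrected first (single-exponential
#' fit on the pre-stimulus segment, see [correct_photobleaching()]). The
#' depletion magnitude is reported as `minus_dfmin`.
#'
#' @param trace A bleach-corrected [fluor_trace()] (channel "cepia").
#' @param protocol A [heat_protocol()].
#' @param bg A [background_estimates()].
#' @param window Window bounds in seconds after pulse onset.
#' @return List of class `burst_metrics` with `dfmin`, `minus_dfmin`,
#'   `t_min_s`.
#' @export
dfmin_cepia <- function(trace, protocol, bg, window = c(2.4, 10)) {
  bs <- baseline(trace, protocol, bg)
  sel <- window_frames(trace, protocol$t_start + window[1],
                       protocol$t_start + window[2], "ER-depletion")
  rel <- (trace$intensity_au[sel] - bs$f_before) / bs$f0
  i <- which.min(rel)
  structure(list(cell_id = trace$cell_id, channel = trace$channel,
                 dfmin = rel[i], minus_dfmin = -rel[i],
                 t_min_s = trace$time_s[sel][i],
                 f_before = bs$f_before, f0 = bs$f0),
            class = "burst_metrics")
}

#' Normalise a burst magnitude by the resting store level
#'
#' Divides `dF_max/F0` by the line's resting ER Ca2+ level relative to wild
#' type, exposing the burst magnitude a full store would have produced
#' (lines with depleted stores under-report their release).
#'
#' @param dfmax Burst magnitude, dF/F0 units.
#' @param resting_store_rel Resting store level relative to WT (> 0).
#' @return The store-normalised magnitude.
#' @export
normalize_by_store <- function(dfmax, resting_store_rel) {
  if (any(resting_store_rel <= 0)) stop("resting_store_rel must be positive")
  dfmax / resting_store_rel
}

#' Correlation between ER depletion and cytosolic burst size
#'
#' Pearson correlation (with two-sided p-value) between per-line mean ER
#' depletion magnitudes (-dF_min/F0) and per-line mean cytosolic burst
#' magnitudes (dF_max/F0).
#'
#' @param group_means_dfmin Numeric vector of per-line mean -dF_min/F0.
#' @param group_means_dfmax Numeric vector of per-line mean dF_max/F0 (same
#'   length, >= 3).
#' @return List with `r` (correlation coefficient) and `p.value`.
#' @export
correlate_er_cytosol <- function(group_means_dfmin, group_means_dfmax) {
  stopifnot(length(group_means_dfmin) == length(group_means_dfmax))
  if (length(group_means_dfmin) < 3L) stop("need at least 3 paired group means")
  ct <- stats::cor.test(group_means_dfmin, group_means_dfmax,
                        method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}
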