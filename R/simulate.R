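#' Generative parameters for one RyR1 cell line
#'
#' Describes how a cell line responds to a local heat pulse in the simulator:
#' the 50% point and width of the sigmoidal burst probability, the burst
#' amplitude distribution and kinetics, the SERCA-uptake dip during heating,
#' the resting ER store level relative to wild type, and the spontaneous
#' event rate.
#'
#' @param name Line label.
#' @param dtth_true Generative heat-sensitivity threshold: the temperature
#'   rise (degC) at which the burst probability is 50%.
#' @param resp_slope Width of the logistic burst-probability curve, degC.
#' @param burst_amp_mean,burst_amp_sd Mean and SD of the burst amplitude in
#'   dF/F0 units (drawn from a normal truncated at 0).
#' @param burst_latency_mode "during_heating" (burst starts shortly after
#'   pulse onset) or "post_recooling" (burst starts after the pulse ends).
#' @param burst_rise_s Burst rise time constant, s (bursts are faster than
#'   ~500 ms).
#' @param serca_dip_frac Fractional intensity drop during heating from
#'   heat-activated Ca2+ reuptake (0 <= x < 1).
#' @param resting_store_rel Resting ER Ca2+ level relative to WT (> 0; leaky
#'   mutants sit below 1).
#' @param spont_rate Spontaneous Ca2+ event rate, events/s.
#' @return An object of class `mutant_params`.
#' @seealso [mutant_preset()] for the built-in cell lines.
#' @export
mutant_params <- function(name = "WT", dtth_true = 5.8, resp_slope = 1,
                          burst_amp_mean = 2, burst_amp_sd = 0.7,
                          burst_latency_mode = c("post_recooling", "during_heating"),
                          burst_rise_s = 0.3, serca_dip_frac = 0.1,
                          resting_store_rel = 1, spont_rate = 0.001) {
  burst_latency_mode <- match.arg(burst_latency_mode)
  stopifnot(dtth_true > 0, resp_slope > 0, burst_amp_mean >= 0,
            burst_amp_sd >= 0, serca_dip_frac >= 0, serca_dip_frac < 1,
            resting_store_rel > 0, spont_rate >= 0, burst_rise_s > 0)
  structure(list(name = name, dtth_true = dtth_true, resp_slope = resp_slope,
                 burst_amp_mean = burst_amp_mean, burst_amp_sd = burst_amp_sd,
                 burst_latency_mode = burst_latency_mode,
                 burst_rise_s = burst_rise_s, serca_dip_frac = serca_dip_frac,
                 resting_store_rel = resting_store_rel,
                 spont_rate = spont_rate),
            class = "mutant_params")
}

#' Built-in cell-line presets
#'
#' Generative parameter sets for HEK293 lines expressing wild-type RyR1 or
#' the malignant-hyperthermia mutants, at base temperatures 24 and 36 degC.
#' The 50% points are the reported heat-sensitivity thresholds per line and
#' base temperature; amplitude, dip and store parameters are modelling
#' choices that reproduce the qualitative phenotypes (see the package
#' vignette).
#'
#' @param name One of "WT", "Q156K", "R164C", "R164L", "Y523S".
#' @param T0 Base temperature: 24 or 36 (degC).
#' @return A [mutant_params()] object.
#' @examples
#' mutant_preset("R164C", 36)$dtth_true  # 1.4
#' @export
mutant_preset <- function(name = c("WT", "Q156K", "R164C", "R164L", "Y523S"),
                          T0 = 36) {
  name <- match.arg(name)
  stopifnot(T0 %in% c(24, 36))
  dtth <- if (T0 == 36) {
    c(WT = 5.8, Q156K = 4.9, R164C = 1.4, R164L = 1.4, Y523S = 4.3)
  } else {
    c(WT = 11.5, Q156K = 7.9, R164C = 1.8, R164L = 1.4, Y523S = 3.8)
  }
  amp <- c(WT = 2.0, Q156K = 2.3, R164C = 3.2, R164L = 3.0, Y523S = 1.6)
  amp_sd <- c(WT = 0.7, Q156K = 0.8, R164C = 1.0, R164L = 1.0, Y523S = 0.6)
  dip <- c(WT = 0.10, Q156K = 0.20, R164C = 0.05, R164L = 0.05, Y523S = 0.20)
  store <- c(WT = 1.0, Q156K = 0.85, R164C = 0.70, R164L = 0.70, Y523S = 0.45)
  latency <- if (T0 == 36) {
    c(WT = "post_recooling", Q156K = "during_heating",
      R164C = "during_heating", R164L = "during_heating",
      Y523S = "post_recooling")
  } else {
    c(WT = "post_recooling", Q156K = "post_recooling",
      R164C = "during_heating", R164L = "during_heating",
      Y523S = "post_recooling")
  }
  mutant_params(name = name, dtth_true = unname(dtth[name]), resp_slope = 1,
                burst_amp_mean = unname(amp[name]),
                burst_amp_sd = unname(amp_sd[name]),
                burst_latency_mode = latency[[name]],
                serca_dip_frac = unname(dip[name]),
                resting_store_rel = unname(store[name]))
}

#' Simulation configuration
#'
#' Bundles everything the synthetic-experiment generator needs: acquisition
#' timing, protocol, cell line, noise and background levels, photobleaching,
#' and the optional temperature dependence of the indicator's Ca2+ affinity
#' (Kd 520 nM at 22 degC, 190 nM at 37 degC for fluo-4; off by default since
#' the analysis operates on raw intensities).
#'
#' @param seed Master seed (integer). Per-cell streams are derived from it by
#'   counter, so adding cells does not reshuffle earlier ones.
#' @param n_cells Number of heated cells.
#' @param distances_um Distances of the heated cells to the heat source, um.
#'   Recycled to `n_cells`. Ignored when a target temperature range is given
#'   to [simulate_cohort()].
#' @param frame_interval_s Frame interval, s.
#' @param total_duration_s Recording length, s (must exceed pulse onset +
#'   20 s so the burst analysis window is covered).
#' @param protocol A [heat_protocol()].
#' @param mutant A [mutant_params()].
#' @param field A [field_model()].
#' @param channel Cytosolic indicator channel for the cells: "fluo4",
#'   "cal520" or "cepia".
#' @param noise_sd Additive Gaussian (shot-like) noise SD, a.u.
#' @param bleach_rate_per_s Photobleaching rate, 1/s.
#' @param i_back Excitation-off background, a.u.
#' @param i_laser_peak Extra IR-scatter background during laser-on frames,
#'   a.u. (a cell-free ROI reads `i_back + i_laser_peak` during the pulse).
#' @param f_baseline_mean,f_baseline_sd Baseline fluorescence distribution
#'   across cells, a.u.
#' @param indicator_kd_22C,indicator_kd_37C Indicator Ca2+ dissociation
#'   constants, nM.
#' @param kd_modulation Apply the Kd(T) saturation factor to cytosolic
#'   signals during heating? Default FALSE.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_cells = 50, distances_um = seq(10, 120, length.out = 50),
                       frame_interval_s = 0.2, total_duration_s = 35,
                       protocol = heat_protocol(), mutant = mutant_preset("WT", 36),
                       field = field_model(), channel = "fluo4",
                       noise_sd = 1.5, bleach_rate_per_s = 0,
                       i_back = 5, i_laser_peak = 3,
                       f_baseline_mean = 100, f_baseline_sd = 10,
                       indicator_kd_22C = 520, indicator_kd_37C = 190,
                       kd_modulation = FALSE) {
  stopifnot(frame_interval_s > 0, total_duration_s > 0, n_cells >= 0,
            noise_sd >= 0, bleach_rate_per_s >= 0, i_back >= 0,
            i_laser_peak >= 0, f_baseline_mean > 0, f_baseline_sd >= 0,
            indicator_kd_22C > 0, indicator_kd_37C > 0)
  stopifnot(inherits(protocol, "heat_protocol"), inherits(mutant, "mutant_params"),
            inherits(field, "field_model"))
  if (total_duration_s <= protocol$t_start + 20) {
    stop("total_duration_s must exceed pulse onset + 20 s")
  }
  seed <- as.integer(seed)
  channel <- match.arg(channel, c("fluo4", "cal520", "cepia"))
  structure(list(seed = seed, n_cells = as.integer(n_cells),
                 distances_um = distances_um,
                 frame_interval_s = frame_interval_s,
                 total_duration_s = total_duration_s,
                 protocol = protocol, mutant = mutant, field = field,
                 channel = channel, noise_sd = noise_sd,
                 bleach_rate_per_s = bleach_rate_per_s,
                 i_back = i_back, i_laser_peak = i_laser_peak,
                 f_baseline_mean = f_baseline_mean,
                 f_baseline_sd = f_baseline_sd,
                 indicator_kd_22C = indicator_kd_22C,
                 indicator_kd_37C = indicator_kd_37C,
                 kd_modulation = kd_modulation),
            class = "sim_config")
}

sim_time_grid <- function(cfg) {
  seq(0, cfg$total_duration_s, by = cfg$frame_interval_s)
}

# derived substream seed; kept well below 2^31
substream_seed <- function(master, offset, k) {
  (as.integer(master) %% 1000000L) * 2000L + offset + k
}

# indicator saturation factor: Kd interpolated linearly in temperature,
# normalised to 1 at T0 (so no effect without heating)
kd_factor <- function(cfg, temp_abs) {
  kd <- function(tc) {
    w <- (tc - 22) / (37 - 22)
    cfg$indicator_kd_22C + w * (cfg$indicator_kd_37C - cfg$indicator_kd_22C)
  }
  kd(cfg$protocol$T0) / kd(temp_abs)
}

#' Simulate one temperature-dye (Eu-TTA) trace
#'
#' Generates a luminescence trace of the temperature-sensitive dye at
#' distance `r` from the heat source: baseline intensity thermally quenched
#' by the local temperature rise, multiplied by photobleaching, plus the
#' excitation-off background, IR-scatter during the pulse, and Gaussian
#' noise. The ground-truth plateau temperature rise is stored in the
#' `"truth"` attribute.
#'
#' @param profile A `temperature_profile` from [simulate_temperature_field()]
#'   (or NULL to compute the field from `cfg`).
#' @param r Distance to the heat source, um.
#' @param cal A [calibration_curve()] with a slope for `cfg$protocol$T0`.
#' @param cfg A [sim_config()].
#' @param seed Seed for the noise stream (default derived from `cfg$seed`).
#' @param cell_id Trace identifier.
#' @return A [fluor_trace()] with channel "eutta" and attribute `truth`
#'   (list with `deltaT_plateau_C`).
#' @export
simulate_eutta_trace <- function(profile = NULL, r, cal, cfg,
                                 seed = NULL, cell_id = "sheet") {
  stopifnot(inherits(cfg, "sim_config"), r > 0)
  slope <- cal_slope(cal, cfg$protocol$T0)  # errors if T0 unsupported
  times <- sim_time_grid(cfg)
  if (is.null(profile)) {
    profile <- simulate_temperature_field(cfg$field, cfg$protocol$laser_power,
                                          r, times, cfg$protocol)
    dT <- profile$deltaT[1, ]
  } else {
    # interpolate the profile at r for each time point
    if (length(profile$distances) == 1L) {
      dT <- profile$deltaT[1, ]
    } else {
      dT <- apply(profile$deltaT, 2, function(col) {
        stats::approx(profile$distances, col, xout = r, rule = 2)$y
      })
    }
    times <- profile$times
  }
  on <- times > cfg$protocol$t_start + 1e-9 &
    times <= cfg$protocol$t_start + cfg$protocol$duration + 1e-9
  bleach <- exp(-cfg$bleach_rate_per_s * times)
  if (is.null(seed)) seed <- substream_seed(cfg$seed, 0L, 1L)
  set.seed(seed)
  noise <- if (cfg$noise_sd > 0) stats::rnorm(length(times), 0, cfg$noise_sd) else 0
  intensity <- cfg$f_baseline_mean * (1 + slope * dT) * bleach +
    cfg$i_back + cfg$i_laser_peak * on + noise
  tr <- fluor_trace(times, intensity, laser_on = on, cell_id = cell_id,
                    channel = "eutta", distance_um = r)
  amp <- field_amplitude(cfg$field, cfg$protocol$laser_power, r)
  attr(tr, "truth") <- list(deltaT_plateau_C = amp)
  tr
}

# unit-peak burst waveform: first-order rise times exponential decay,
# rescaled so its maximum on the frame grid is exactly 1
burst_shape <- function(times, t_onset, rise_s, decay_s = 8) {
  s <- numeric(length(times))
  post <- times >= t_onset
  dt <- times[post] - t_onset
  s[post] <- (1 - exp(-dt / rise_s)) * exp(-dt / decay_s)
  m <- max(s)
  if (m > 0) s <- s / m
  s
}

#' Simulate one cell's Ca2+ indicator trace
#'
#' Cytosolic channels ("fluo4", "cal520"): a heat-induced Ca2+ burst occurs
#' with probability `plogis((deltaT - dtth_true)/resp_slope)` (zero when the
#' cell is unheated); if it occurs its amplitude is drawn from a truncated
#' normal and its onset follows the line's latency mode. A multiplicative
#' SERCA-uptake dip applies during the pulse. The ER channel ("cepia") shows
#' thermal quenching during the pulse and, in bursting cells, a secondary
#' store-depletion dip reaching its minimum about 5 s after pulse cessation,
#' with depth proportional to the burst amplitude and inversely proportional
#' to the resting store level. All channels add photobleaching, backgrounds,
#' IR scatter and Gaussian noise.
#'
#' @param deltaT_at_cell Plateau temperature rise at the cell, degC (>= 0).
#' @param mutant A [mutant_params()].
#' @param cfg A [sim_config()].
#' @param channel "fluo4", "cal520" or "cepia".
#' @param seed Integer seed for this cell's random stream.
#' @param cell_id Trace identifier.
#' @param heated Logical; unheated reference cells get no laser-on frames,
#'   no scatter and no heat-induced burst.
#' @return A [fluor_trace()] with attribute `truth`: list with `burst` (0/1),
#'   `amp_true`, `deltaT_true_C`.
#' @export
simulate_cell_trace <- function(deltaT_at_cell, mutant, cfg,
                                channel = cfg$channel, seed = cfg$seed,
                                cell_id = "cell", heated = TRUE) {
  stopifnot(inherits(mutant, "mutant_params"), inherits(cfg, "sim_config"),
            deltaT_at_cell >= 0)
  channel <- match.arg(channel, c("fluo4", "cal520", "cepia"))
  times <- sim_time_grid(cfg)
  prot <- cfg$protocol
  t_off <- prot$t_start + prot$duration
  on <- heated & times > prot$t_start + 1e-9 & times <= t_off + 1e-9
  g <- if (heated) pulse_gate(cfg$field, times, prot) else numeric(length(times))
  dT_t <- deltaT_at_cell * g

  set.seed(as.integer(seed))
  f_base <- max(10, stats::rnorm(1, cfg$f_baseline_mean, cfg$f_baseline_sd))
  p_burst <- if (heated && deltaT_at_cell > 0) {
    stats::plogis((deltaT_at_cell - mutant$dtth_true) / mutant$resp_slope)
  } else 0
  burst <- stats::runif(1) < p_burst
  amp <- 0
  ca <- rep(1, length(times))
  if (burst) {
    repeat {  # truncated normal, amplitude >= 0
      amp <- stats::rnorm(1, mutant$burst_amp_mean, mutant$burst_amp_sd)
      if (amp >= 0) break
    }
    t_onset <- if (mutant$burst_latency_mode == "during_heating") {
      prot$t_start + 0.2 + stats::runif(1, 0, 0.3)
    } else {
      t_off + stats::runif(1, 0, 0.5)
    }
  }

  if (channel %in% c("fluo4", "cal520")) {
    if (burst) ca <- ca + amp * burst_shape(times, t_onset, mutant$burst_rise_s)
    # spontaneous transients (small, for fluctuation modelling)
    n_ev <- stats::rpois(1, mutant$spont_rate * cfg$total_duration_s)
    if (n_ev > 0) {
      for (te in stats::runif(n_ev, 0, cfg$total_duration_s)) {
        ca <- ca + abs(stats::rnorm(1, 0.15, 0.05)) *
          burst_shape(times, te, mutant$burst_rise_s, decay_s = 3)
      }
    }
    if (cfg$kd_modulation) {
      ca <- 1 + (ca - 1) * kd_factor(cfg, prot$T0 + dT_t)
    }
    # SERCA-uptake dip: rectangular during laser-on frames
    dip <- 1 - mutant$serca_dip_frac * on
    ca <- ca * dip
  } else {  # cepia: ER store signal
    quench <- 1 - 0.02 * dT_t                         # thermal quenching
    depth <- if (burst) {
      min(0.9, 0.4 * amp / mutant$resting_store_rel)  # store depletion
    } else 0
    dip2 <- 1 - depth * exp(-((times - (t_off + 5))^2) / (2 * 1.5^2)) *
      (times > t_off)
    ca <- quench * dip2
  }

  bleach <- exp(-cfg$bleach_rate_per_s * times)
  noise <- if (cfg$noise_sd > 0) stats::rnorm(length(times), 0, cfg$noise_sd) else 0
  intensity <- f_base * ca * bleach + cfg$i_back + cfg$i_laser_peak * on + noise
  tr <- fluor_trace(times, intensity, laser_on = on, cell_id = cell_id,
                    channel = channel, distance_um = NA_real_)
  attr(tr, "truth") <- list(burst = as.integer(burst), amp_true = amp,
                            deltaT_true_C = if (heated) deltaT_at_cell else 0)
  tr
}

#' Simulate a full microheating cohort
#'
#' Generates a ground-truthed synthetic experiment: a temperature-dye sheet
#' measurement at several distances, one cell-free background ROI, `n_cells`
#' heated cells at their distances (each cell's temperature rise taken from
#' the field model at its distance), and optionally unheated reference cells
#' for fluctuation modelling. Fully reproducible from `cfg$seed`; per-cell
#' streams are derived by counter so growing the cohort does not reshuffle
#' existing cells.
#'
#' @param cfg A [sim_config()].
#' @param n_unheated Number of unheated reference cells.
#' @param deltaT_range Optional length-2 numeric: draw each heated cell's
#'   plateau temperature rise uniformly from this range (degC) and place the
#'   cell at the matching distance, instead of using `cfg$distances_um`.
#' @param n_sheet Number of sheet ROI distances for the dye measurement.
#' @param sheet_noise_sd Noise SD for the sheet traces (default 0: the sheet
#'   calibration is effectively noise-free at the scale of cell noise).
#' @param cal Calibration curve used only to emulate dye quenching.
#' @return An object of class `hicr_cohort`: list with `traces` (list of
#'   [fluor_trace()]), `roi` (data frame: cell_id, x_px, y_px, radius_px,
#'   distance_um), `truth` (data frame: cell_id, deltaT_true_C, burst,
#'   amp_true) and `cfg`.
#' @export
simulate_cohort <- function(cfg, n_unheated = 0, deltaT_range = NULL,
                            n_sheet = 8, sheet_noise_sd = 0,
                            cal = calibration_curve()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cells == 0L) stop("n_cells must be positive")
  prot <- cfg$protocol
  master <- cfg$seed

  # heated-cell temperature rises and distances
  if (!is.null(deltaT_range)) {
    stopifnot(length(deltaT_range) == 2L, deltaT_range[2] > deltaT_range[1])
    # the requested rises must be reachable by the softened field (r -> 0)
    max_reachable <- field_amplitude(cfg$field, prot$laser_power, 0)
    if (deltaT_range[2] > max_reachable) {
      stop(sprintf(paste("deltaT_range[2] = %g degC exceeds the maximum rise",
                         "%.2f degC reachable at this laser power; increase",
                         "protocol$laser_power"),
                   deltaT_range[2], max_reachable))
    }
    set.seed(substream_seed(master, 0L, 0L))
    dT_cells <- stats::runif(cfg$n_cells, max(deltaT_range[1], 1e-3),
                             deltaT_range[2])
    r_cells <- field_distance_for(cfg$field, prot$laser_power, dT_cells)
  } else {
    r_cells <- rep_len(cfg$distances_um, cfg$n_cells)
    dT_cells <- field_amplitude(cfg$field, prot$laser_power, r_cells)
  }

  traces <- list()
  truth <- list()

  # temperature-dye sheet at log-spaced distances covering the cells
  r_sheet <- exp(seq(log(max(min(r_cells), 0.5)), log(max(r_cells, 50)),
                     length.out = n_sheet))
  sheet_cfg <- cfg
  sheet_cfg$noise_sd <- sheet_noise_sd
  sheet_cfg$bleach_rate_per_s <- 0
  for (j in seq_len(n_sheet)) {
    id <- sprintf("sheet%02d", j)
    traces[[id]] <- simulate_eutta_trace(NULL, r_sheet[j], cal, sheet_cfg,
                                         seed = substream_seed(master, 100L, j),
                                         cell_id = id)
  }

  # cell-free background ROI (scatter only)
  times <- sim_time_grid(cfg)
  on <- times > prot$t_start + 1e-9 & times <= prot$t_start + prot$duration + 1e-9
  set.seed(substream_seed(master, 300L, 1L))
  bg_noise <- if (cfg$noise_sd > 0) stats::rnorm(length(times), 0, cfg$noise_sd) else 0
  traces[["bg01"]] <- fluor_trace(times, cfg$i_back + cfg$i_laser_peak * on + bg_noise,
                                  laser_on = on, cell_id = "bg01",
                                  channel = cfg$channel, distance_um = NA_real_)

  for (k in seq_len(cfg$n_cells)) {
    id <- sprintf("cell%04d", k)
    tr <- simulate_cell_trace(dT_cells[k], cfg$mutant, cfg,
                              channel = cfg$channel,
                              seed = substream_seed(master, 400L, k),
                              cell_id = id, heated = TRUE)
    tr$distance_um <- r_cells[k]
    traces[[id]] <- tr
    truth[[id]] <- data.frame(cell_id = id,
                              deltaT_true_C = dT_cells[k],
                              burst = attr(tr, "truth")$burst,
                              amp_true = attr(tr, "truth")$amp_true)
  }

  for (k in seq_len(n_unheated)) {
    id <- sprintf("spont%04d", k)
    tr <- simulate_cell_trace(0, cfg$mutant, cfg, channel = cfg$channel,
                              seed = substream_seed(master, 900L, k),
                              cell_id = id, heated = FALSE)
    traces[[id]] <- tr
    truth[[id]] <- data.frame(cell_id = id, deltaT_true_C = 0,
                              burst = attr(tr, "truth")$burst,
                              amp_true = attr(tr, "truth")$amp_true)
  }

  # ROI geometry: heat source at origin, cells on a spiral at their distance
  ids <- names(traces)
  r_all <- vapply(traces, function(t) t$distance_um, numeric(1))
  ang <- 2.399963 * seq_along(ids)  # golden angle
  roi <- data.frame(cell_id = ids,
                    x_px = ifelse(is.na(r_all), NA_real_, r_all * cos(ang)),
                    y_px = ifelse(is.na(r_all), NA_real_, r_all * sin(ang)),
                    radius_px = 4,
                    distance_um = r_all,
                    row.names = NULL)

  structure(list(traces = traces, roi = roi,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 cfg = cfg),
            class = "hicr_cohort")
}

#' @export
print.hicr_cohort <- function(x, ...) {
  n_cell <- sum(grepl("^cell", names(x$traces)))
  n_spont <- sum(grepl("^spont", names(x$traces)))
  n_sheet <- sum(grepl("^sheet", names(x$traces)))
  cat(sprintf("<hicr_cohort: %d heated, %d unheated, %d sheet ROIs, line %s, T0 = %g degC>\n",
              n_cell, n_spont, n_sheet, x$cfg$mutant$name, x$cfg$protocol$T0))
  invisible(x)
}
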