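# shared fixtures: small noise-free traces and default analysis objects

default_prot <- function(...) heat_protocol(laser_power = 25.6, T0 = 24, ...)

# constant-intensity trace on the default 0.2-s grid
const_trace <- function(value = 100, duration = 35, dt = 0.2,
                        protocol = default_prot(), laser = TRUE, ...) {
  times <- seq(0, duration, by = dt)
  on <- laser & times > protocol$t_start + 1e-9 &
    times <= protocol$t_start + protocol$duration + 1e-9
  fluor_trace(times, rep(value, length(times)), laser_on = on, ...)
}

# trace with a given intensity profile as a function of time
shaped_trace <- function(f, duration = 35, dt = 0.2,
                         protocol = default_prot(), laser = TRUE, ...) {
  times <- seq(0, duration, by = dt)
  on <- laser & times > protocol$t_start + 1e-9 &
    times <= protocol$t_start + protocol$duration + 1e-9
  fluor_trace(times, f(times), laser_on = on, ...)
}

noise_free_cfg <- function(...) {
  args <- list(...)
  defaults <- list(seed = 1, n_cells = 5, noise_sd = 0, bleach_rate_per_s = 0,
                   i_back = 0, i_laser_peak = 0, f_baseline_sd = 0)
  do.call(sim_config, utils::modifyList(defaults, args))
}

no_bg <- function() background_estimates(0, 0)
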