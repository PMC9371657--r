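test_that("dye trace quench matches the calibration slope at a 1 degC plateau", {
  # place the dye ROI where the plateau is exactly 1 degC
  cfg <- noise_free_cfg(protocol = heat_protocol(T0 = 24))
  cal <- calibration_curve()
  r1 <- field_distance_for(cfg$field, cfg$protocol$laser_power, 1)
  tr <- simulate_eutta_trace(NULL, r1, cal, cfg)
  expect_equal(attr(tr, "truth")$deltaT_plateau_C, 1, tolerance = 1e-9)
  expect_equal(quench_ratio(tr, cfg$protocol, no_bg()), -0.027, tolerance = 1e-9)
})

test_that("dye trace is flat without heating and bleaches exponentially", {
  cfg <- noise_free_cfg(protocol = heat_protocol(T0 = 24, laser_power = 0),
                        i_back = 4, total_duration_s = 101,
                        frame_interval_s = 0.5)
  tr <- simulate_eutta_trace(NULL, 50, calibration_curve(), cfg)
  expect_true(all(tr$intensity_au == cfg$f_baseline_mean + 4))
  cfgb <- noise_free_cfg(protocol = heat_protocol(T0 = 24, laser_power = 0),
                         bleach_rate_per_s = 0.01, total_duration_s = 101,
                         frame_interval_s = 0.5)
  trb <- simulate_eutta_trace(NULL, 50, calibration_curve(), cfgb)
  i100 <- which(abs(trb$time_s - 100) < 1e-9)
  expect_equal(trb$intensity_au[i100] / trb$intensity_au[1], exp(-1),
               tolerance = 1e-12)
})

test_that("an unheated noise-free cell shows no burst and zero dfmax", {
  cfg <- noise_free_cfg(mutant = mutant_params(spont_rate = 0))
  tr <- simulate_cell_trace(0, cfg$mutant, cfg, seed = 3, heated = TRUE)
  expect_identical(attr(tr, "truth")$burst, 0L)
  m <- dfmax(tr, cfg$protocol, no_bg())
  expect_equal(m$dfmax, 0)
})

test_that("burst fraction at the generative midpoint is one half", {
  cfg <- noise_free_cfg(mutant = mutant_params(dtth_true = 4, spont_rate = 0))
  hits <- vapply(1:4000, function(s) {
    attr(simulate_cell_trace(4, cfg$mutant, cfg, seed = s), "truth")$burst
  }, integer(1))
  expect_equal(mean(hits), 0.5, tolerance = 0.025)
})

test_that("the SERCA dip scales the in-pulse intensity by construction", {
  mut <- mutant_params(dtth_true = 100, serca_dip_frac = 0.1, spont_rate = 0)
  cfg <- noise_free_cfg(mutant = mut)
  tr <- simulate_cell_trace(1, mut, cfg, seed = 5)
  on <- tr$laser_on
  expect_equal(mean(tr$intensity_au[on]) / tr$intensity_au[1], 0.9,
               tolerance = 1e-9)
})

test_that("ER channel reaches its depletion minimum about 5 s after the pulse", {
  mut <- mutant_params(dtth_true = 0.5, resp_slope = 0.01, spont_rate = 0,
                       burst_amp_mean = 2, burst_amp_sd = 0)
  cfg <- noise_free_cfg(mutant = mut, channel = "cepia")
  tr <- simulate_cell_trace(5, mut, cfg, channel = "cepia", seed = 7)
  expect_identical(attr(tr, "truth")$burst, 1L)
  post <- tr$time_s > 12.4  # after the quench epoch
  t_min <- tr$time_s[post][which.min(tr$intensity_au[post])]
  expect_equal(t_min, 12 + 5, tolerance = 0.5)
})

test_that("ER depletion depth grows with burst amplitude and shrinking store", {
  depth_for <- function(amp, store) {
    mut <- mutant_params(dtth_true = 0.5, resp_slope = 0.01, spont_rate = 0,
                         burst_amp_mean = amp, burst_amp_sd = 0,
                         resting_store_rel = store)
    cfg <- noise_free_cfg(mutant = mut, channel = "cepia")
    tr <- simulate_cell_trace(5, mut, cfg, channel = "cepia", seed = 11)
    m <- dfmin_cepia(tr, cfg$protocol, no_bg())
    m$minus_dfmin
  }
  expect_gt(depth_for(2, 1), depth_for(1, 1))
  expect_gt(depth_for(1, 0.5), depth_for(1, 1))
})

test_that("unknown channel is rejected", {
  cfg <- noise_free_cfg()
  expect_error(simulate_cell_trace(1, cfg$mutant, cfg, channel = "gcamp"))
})

test_that("cohorts are bitwise reproducible from the master seed", {
  cfg <- sim_config(seed = 99, n_cells = 12)
  a <- simulate_cohort(cfg, n_unheated = 4)
  b <- simulate_cohort(cfg, n_unheated = 4)
  expect_identical(a, b)
  expect_error(simulate_cohort(sim_config(n_cells = 0)), "positive")
})

test_that("equal distances give equal ground-truth temperature rises", {
  cfg <- sim_config(seed = 5, n_cells = 20, distances_um = rep(30, 20))
  coh <- simulate_cohort(cfg)
  dts <- coh$truth$deltaT_true_C[grepl("^cell", coh$truth$cell_id)]
  expect_true(all(dts == dts[1]))
})

test_that("growing the cohort preserves earlier cells' traces", {
  cfg_small <- sim_config(seed = 7, n_cells = 10)
  cfg_big <- sim_config(seed = 7, n_cells = 20)
  a <- simulate_cohort(cfg_small)
  b <- simulate_cohort(cfg_big)
  expect_identical(a$traces[["cell0003"]], b$traces[["cell0003"]])
})

test_that("a more heat-sensitive line yields more responders at equal exposure", {
  n_burst <- function(dtth, seed) {
    mut <- mutant_params(dtth_true = dtth, spont_rate = 0)
    cfg <- sim_config(seed = seed, n_cells = 150, mutant = mut)
    coh <- simulate_cohort(cfg, deltaT_range = c(0.5, 10))
    sum(coh$truth$burst[grepl("^cell", coh$truth$cell_id)])
  }
  for (s in 1:3) expect_gt(n_burst(2, s), n_burst(8, s))
})

test_that("unreachable temperature ranges are rejected", {
  cfg <- sim_config(seed = 1, n_cells = 10)
  expect_error(simulate_cohort(cfg, deltaT_range = c(0, 20)), "laser_power")
})
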