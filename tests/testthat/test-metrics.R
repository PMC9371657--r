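test_that("baseline takes the designated frame and subtracts the background", {
  prot <- default_prot()
  tr <- const_trace(100)
  bs <- baseline(tr, prot, background_estimates(5, 5))
  expect_equal(bs$f_before, 100)
  expect_equal(bs$f0, 95)
  # no smoothing: the single designated frame's value is used verbatim
  set.seed(2)
  noisy <- shaped_trace(function(t) 100 + sin(37 * t))
  i10 <- max(which(noisy$time_s <= 10))
  expect_equal(baseline(noisy, prot, no_bg())$f_before,
               noisy$intensity_au[i10])
  # trace starting after the onset frame
  late <- fluor_trace(seq(11, 30, 0.2), rep(100, 96))
  expect_error(baseline(late, prot, no_bg()), "no frame")
  expect_error(baseline(tr, prot, background_estimates(100, 0)),
               "dead baseline")
})

test_that("scatter correction touches only laser-on frames", {
  prot <- default_prot()
  tr <- const_trace(100, protocol = prot)
  out <- scatter_correct(tr, background_estimates(0, 3), prot)
  expect_equal(out$intensity_au[out$laser_on], rep(97, sum(out$laser_on)))
  expect_equal(out$intensity_au[!out$laser_on], rep(100, sum(!out$laser_on)))
  # zero scatter is the identity
  expect_identical(scatter_correct(tr, no_bg(), prot), tr)
})

test_that("scatter correction recovers the scatter-free twin exactly", {
  mut <- mutant_params(dtth_true = 0.5, resp_slope = 0.01, spont_rate = 0,
                       burst_amp_sd = 0, burst_latency_mode = "during_heating")
  cfg_clean <- noise_free_cfg(mutant = mut)
  cfg_scatter <- noise_free_cfg(mutant = mut, i_laser_peak = 7)
  clean <- simulate_cell_trace(3, mut, cfg_clean, seed = 4)
  dirty <- simulate_cell_trace(3, mut, cfg_scatter, seed = 4)
  fixed <- scatter_correct(dirty, background_estimates(0, 7), cfg_scatter$protocol)
  expect_equal(fixed$intensity_au, clean$intensity_au, tolerance = 1e-12)
})

test_that("dfmax implements the windowed maximum of dF/F0", {
  prot <- default_prot()
  expect_equal(dfmax(const_trace(100), prot, no_bg())$dfmax, 0)
  tr <- shaped_trace(function(t) 100 + 50 * (abs(t - 15) < 0.01))
  m <- dfmax(tr, prot, no_bg())
  expect_equal(m$dfmax, 0.5)
  expect_equal(m$t_peak_s, 15)
  # a peak after the window is excluded
  tr2 <- shaped_trace(function(t) 100 + 80 * (abs(t - 35) < 0.01) +
                        20 * (abs(t - 15) < 0.01), duration = 40)
  expect_equal(dfmax(tr2, prot, no_bg())$dfmax, 0.2)
  # incomplete window errors
  short <- const_trace(100, duration = 25)
  expect_error(dfmax(short, prot, no_bg()), "window")
})

test_that("dfmax is invariant under joint rescaling of trace and background", {
  prot <- default_prot()
  tr <- shaped_trace(function(t) 100 + 40 * exp(-(t - 14)^2))
  bg <- background_estimates(10, 10)
  m1 <- dfmax(tr, prot, bg)$dfmax
  tr3 <- tr
  tr3$intensity_au <- 3 * tr3$intensity_au
  m3 <- dfmax(tr3, prot, background_estimates(30, 30))$dfmax
  expect_equal(m1, m3, tolerance = 1e-12)
})

test_that("dfmax dominates the per-frame relative change within the window", {
  prot <- default_prot()
  set.seed(9)
  tr <- shaped_trace(function(t) 100 + cumsum(rnorm(length(t))) / 10)
  bs <- baseline(tr, prot, no_bg())
  m <- dfmax(tr, prot, no_bg())
  sel <- tr$time_s >= 10 & tr$time_s <= 30
  rel <- (tr$intensity_au[sel] - bs$f_before) / bs$f0
  expect_true(all(m$dfmax >= rel))
})

test_that("noise-free generator bursts are measured at exactly their amplitude", {
  for (a in c(0.5, 1.5, 3)) {
    mut <- mutant_params(dtth_true = 0.5, resp_slope = 0.01, spont_rate = 0,
                         burst_amp_mean = a, burst_amp_sd = 0,
                         serca_dip_frac = 0)
    cfg <- noise_free_cfg(mutant = mut)
    tr <- simulate_cell_trace(5, mut, cfg, seed = 2)
    expect_equal(dfmax(tr, cfg$protocol, no_bg())$dfmax, a, tolerance = 1e-9)
  }
})

test_that("spontaneous fluctuation statistic uses the 10-30 s closed window", {
  bg <- no_bg()
  expect_equal(spontaneous_dfmax(const_trace(100, laser = FALSE), bg), 0)
  tr <- shaped_trace(function(t) 100 + 20 * (abs(t - 20) < 0.01), laser = FALSE)
  expect_equal(spontaneous_dfmax(tr, bg), 0.2)
  # a maximum at exactly 30 s is included
  tr30 <- shaped_trace(function(t) 100 + 20 * (abs(t - 30) < 0.01), laser = FALSE)
  expect_equal(spontaneous_dfmax(tr30, bg), 0.2)
  # a maximum before the window is ignored
  tr5 <- shaped_trace(function(t) 100 + 20 * (abs(t - 5) < 0.01), laser = FALSE)
  expect_equal(spontaneous_dfmax(tr5, bg), 0)
})

test_that("ER depletion statistic excludes the quench epoch", {
  prot <- default_prot()
  expect_equal(dfmin_cepia(const_trace(100), prot, no_bg())$dfmin, 0)
  tr <- shaped_trace(function(t) 100 - 20 * (abs(t - 16) < 0.01))
  m <- dfmin_cepia(tr, prot, no_bg())
  expect_equal(m$dfmin, -0.2)
  expect_equal(m$minus_dfmin, 0.2)
  # a dip during the pulse (before onset + 2.4 s) is outside the window
  trq <- shaped_trace(function(t) 100 - 30 * (t > 10 & t <= 12))
  expect_equal(dfmin_cepia(trq, prot, no_bg())$dfmin, 0)
})

test_that("store normalisation rescales burst magnitudes", {
  expect_equal(normalize_by_store(2, 1), 2)
  expect_equal(normalize_by_store(2, 0.5), 4)
  expect_error(normalize_by_store(2, 0), "positive")
})

test_that("ER/cytosol correlation behaves on exact and simulated inputs", {
  expect_equal(correlate_er_cytosol(c(1, 2, 3, 4), c(2, 4, 6, 8))$r, 1)
  expect_equal(correlate_er_cytosol(c(1, 2, 3, 4), c(8, 6, 4, 2))$r, -1)
  expect_error(correlate_er_cytosol(c(1, 2), c(1, 2)), "at least 3")
})

test_that("lines coupled through burst amplitude correlate ER and cytosol", {
  # five lines differing only in burst amplitude; ER depth ~ amplitude
  amps <- c(0.8, 1.4, 2.0, 2.6, 3.2)
  rs <- vapply(1:5, function(rep_i) {
    mdfmax <- mdfmin <- numeric(length(amps))
    for (i in seq_along(amps)) {
      mut <- mutant_params(dtth_true = 1, resp_slope = 0.5,
                           burst_amp_mean = amps[i], burst_amp_sd = 0.3,
                           spont_rate = 0)
      cfg <- sim_config(seed = 1000 * rep_i + i, n_cells = 40, mutant = mut,
                        noise_sd = 1, distances_um = rep(15, 40))
      cyt <- simulate_cohort(cfg)
      cfg2 <- cfg; cfg2$channel <- "cepia"; cfg2$seed <- cfg$seed + 500L
      er <- simulate_cohort(cfg2)
      bg <- background_estimates(cfg$i_back, cfg$i_back + cfg$i_laser_peak)
      mdfmax[i] <- mean(vapply(cyt$traces[grepl("^cell", names(cyt$traces))],
        function(tr) dfmax(scatter_correct(tr, bg, cfg$protocol),
                           cfg$protocol, bg)$dfmax, numeric(1)))
      mdfmin[i] <- mean(vapply(er$traces[grepl("^cell", names(er$traces))],
        function(tr) dfmin_cepia(correct_photobleaching(tr, c(0, 10)),
                                 cfg$protocol, bg)$minus_dfmin, numeric(1)))
    }
    correlate_er_cytosol(mdfmin, mdfmax)$r
  }, numeric(1))
  expect_gt(median(rs), 0.9)
})
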